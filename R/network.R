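#' Cis target prediction
#'
#' A coding gene is a cis target of a lncRNA locus when the gap between
#' their genomic spans is at most the window (inclusive; 100 kb by
#' default), with gap 0 for overlapping or abutting spans.  The search is
#' strand-agnostic and restricted to the lncRNA's chromosome.
#'
#' @param annot a \linkS4class{TranscriptAnnotation} containing both the
#'   lncRNA candidates and the coding genes.
#' @param lncIds lncRNA transcript ids to search around.
#' @param config a \linkS4class{PipelineConfig} (uses \code{cisWindowBp}).
#' @return data.frame of edges: lncrna, gene, mode = "cis", distance_bp.
#' @export
cisTargets <- function(annot, lncIds, config = pipelineConfig()) {
    meta <- annot@txMeta
    mrnaGenes <- unique(meta$gene_id[meta$biotype == "mRNA"])
    gspan <- annot@genes[names(annot@genes) %in% mrnaGenes]
    if (!length(gspan) || !length(lncIds))
        return(data.frame(lncrna = character(), gene = character(),
                          mode = character(), distance_bp = integer()))
    spans <- unlist(range(annot@exons[lncIds]))
    hits <- GenomicRanges::findOverlaps(
        spans, gspan, maxgap = config@cisWindowBp, ignore.strand = TRUE)
    if (!length(hits))
        return(data.frame(lncrna = character(), gene = character(),
                          mode = character(), distance_bp = integer()))
    d <- GenomicRanges::distance(spans[S4Vectors::queryHits(hits)],
                                 gspan[S4Vectors::subjectHits(hits)],
                                 ignore.strand = TRUE)
    keep <- d <= config@cisWindowBp
    data.frame(lncrna = lncIds[S4Vectors::queryHits(hits)][keep],
               gene = names(gspan)[S4Vectors::subjectHits(hits)][keep],
               mode = "cis", distance_bp = as.integer(d[keep]),
               row.names = NULL)
}

#' Co-expression target prediction
#'
#' Pairs each lncRNA with the coding genes whose expression profile it
#' tracks: an edge is called when |Pearson r| on log2(FPKM + 1) strictly
#' exceeds the cut (0.95 by default); the signed r is recorded.
#' Zero-variance features are skipped with a warning.
#'
#' @param se a \linkS4class{StageExpression} containing both feature sets.
#' @param lncIds,geneIds row subsets for the two sides.
#' @param config a \linkS4class{PipelineConfig} (uses
#'   \code{coexprAbsRMin}).
#' @return data.frame of edges: lncrna, gene, mode = "coexpression", r.
#' @export
coexpressionTargets <- function(se, lncIds, geneIds,
                                config = pipelineConfig()) {
    x <- log2Fpkm(se)
    empty <- data.frame(lncrna = character(), gene = character(),
                        mode = character(), r = numeric())
    if (!length(lncIds) || !length(geneIds)) return(empty)
    xl <- x[lncIds, , drop = FALSE]
    xg <- x[geneIds, , drop = FALSE]
    okL <- apply(xl, 1, stats::sd) > 0
    okG <- apply(xg, 1, stats::sd) > 0
    if (!all(okL) || !all(okG))
        warning("skipping ", sum(!okL) + sum(!okG),
                " zero-variance feature(s)")
    xl <- xl[okL, , drop = FALSE]; xg <- xg[okG, , drop = FALSE]
    if (!nrow(xl) || !nrow(xg)) return(empty)
    r <- stats::cor(t(xl), t(xg))
    idx <- which(abs(r) > config@coexprAbsRMin, arr.ind = TRUE)
    if (!nrow(idx)) return(empty)
    data.frame(lncrna = rownames(r)[idx[, 1]],
               gene = colnames(r)[idx[, 2]],
               mode = "coexpression", r = r[idx], row.names = NULL)
}

#' Assemble the bipartite lncRNA-mRNA target network
#'
#' Admits a lncRNA node when its differential-expression results show some
#' stage pair with p below \code{deAlpha} and a maximal |log2 fold change|
#' of at least log2(\code{fcMin}) over all pairs (|FC| > 2 on the linear
#' scale).  Edges from both evidence modes are restricted to admitted
#' lncRNAs; duplicate (lncRNA, gene) pairs collapse into one edge keeping
#' both evidence records (mode \code{cis+coexpression}).
#'
#' @param deResults list of per-pair DE tables (\code{\link{deUnion}}
#'   \code{$results}) covering the candidate lncRNAs.
#' @param cisEdges,coexprEdges edge tables from \code{\link{cisTargets}}
#'   and \code{\link{coexpressionTargets}}.
#' @param config a \linkS4class{PipelineConfig}.
#' @return a \linkS4class{TargetNetwork}.
#' @export
buildTargetNetwork <- function(deResults, cisEdges, coexprEdges,
                               config = pipelineConfig()) {
    all <- do.call(rbind, c(deResults, make.row.names = FALSE))
    lncIds <- unique(c(cisEdges$lncrna, coexprEdges$lncrna))
    de <- all[all$feature_id %in% lncIds, , drop = FALSE]
    anySig <- tapply(de$p_value < config@deAlpha, de$feature_id, any)
    maxFc <- tapply(abs(de$log2_fc), de$feature_id, max)
    admitted <- names(anySig)[unlist(anySig) &
                              unlist(maxFc) >= log2(config@fcMin)]
    if (is.null(admitted)) admitted <- character()
    ce <- cisEdges[cisEdges$lncrna %in% admitted, , drop = FALSE]
    xe <- coexprEdges[coexprEdges$lncrna %in% admitted, , drop = FALSE]
    if (nrow(ce)) { ce$r <- NA_real_ }
    if (nrow(xe)) { xe$distance_bp <- NA_integer_ }
    cols <- c("lncrna", "gene", "mode", "distance_bp", "r")
    edges <- rbind(
        if (nrow(ce)) ce[, cols] else NULL,
        if (nrow(xe)) xe[, cols] else NULL)
    if (is.null(edges))
        edges <- data.frame(lncrna = character(), gene = character(),
                            mode = character(), distance_bp = integer(),
                            r = numeric())
    if (nrow(edges)) {
        key <- paste(edges$lncrna, edges$gene, sep = "\r")
        dup <- key[duplicated(key)]
        if (length(dup)) {
            merged <- do.call(rbind, lapply(unique(dup), function(k) {
                g <- edges[key == k, , drop = FALSE]
                data.frame(lncrna = g$lncrna[1], gene = g$gene[1],
                           mode = "cis+coexpression",
                           distance_bp = g$distance_bp[
                               which(!is.na(g$distance_bp))[1]],
                           r = g$r[which(!is.na(g$r))[1]])
            }))
            edges <- rbind(edges[!key %in% dup, , drop = FALSE], merged)
        }
        edges <- edges[order(edges$lncrna, edges$gene), , drop = FALSE]
        rownames(edges) <- NULL
    }
    lncNodes <- sort(unique(edges$lncrna))
    mrnaNodes <- sort(unique(edges$gene))
    deg <- integer()
    if (nrow(edges)) {
        tabs <- c(table(edges$lncrna), table(edges$gene))
        deg <- stats::setNames(as.integer(tabs), names(tabs))
    }
    new("TargetNetwork", edges = edges, lncNodes = lncNodes,
        mrnaNodes = mrnaNodes, degree = deg)
}

#' Hub lncRNA extraction
#'
#' Hubs are lncRNA nodes whose degree strictly exceeds the cut (degree >
#' 10 by default), ranked by decreasing degree with lexicographic
#' tie-break; each hub's star subnetwork (its incident edges) is returned.
#'
#' @param network a \linkS4class{TargetNetwork}.
#' @param config a \linkS4class{PipelineConfig} (uses
#'   \code{hubMinDegree}).
#' @return list: \code{hubs} (data.frame lncrna, degree),
#'   \code{subnetworks} (named list of edge tables).
#' @export
hubLncrnas <- function(network, config = pipelineConfig()) {
    deg <- network@degree[network@lncNodes]
    hub <- deg[!is.na(deg) & deg > config@hubMinDegree]
    ord <- order(-hub, names(hub))
    hub <- hub[ord]
    subs <- lapply(names(hub), function(h)
        network@edges[network@edges$lncrna == h, , drop = FALSE])
    names(subs) <- names(hub)
    list(hubs = data.frame(lncrna = names(hub),
                           degree = as.integer(hub), row.names = NULL),
         subnetworks = subs)
}

#' Convert a target network to an igraph object
#'
#' Convenience for export (e.g. GraphML via
#' \code{igraph::write_graph}); requires the \pkg{igraph} package.
#'
#' @param network a \linkS4class{TargetNetwork}.
#' @return an igraph bipartite graph with a \code{type} vertex attribute.
#' @export
asIgraph <- function(network) {
    if (!requireNamespace("igraph", quietly = TRUE))
        stop("the igraph package is required for graph export")
    g <- igraph::graph_from_data_frame(
        network@edges,
        vertices = data.frame(
            name = c(network@lncNodes, network@mrnaNodes),
            type = c(rep(TRUE, length(network@lncNodes)),
                     rep(FALSE, length(network@mrnaNodes)))),
        directed = FALSE)
    g
}
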