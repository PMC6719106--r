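## Synthetic fixture bundle with known ground truth.
##
## The generator emulates a staged bulk RNA-seq survey: a compact genome of
## coding genes with lncRNA loci planted in all three positional classes,
## an FPKM matrix over 7 stages x 3 replicates in which a few co-expression
## modules with early / late / single-stage-peaked step profiles are
## planted, plus the side tables the identification and conservation
## stages consume.  Every piece is deterministic in the design seed.

GENE_SPACING <- 10000L   # bp between consecutive coding-gene starts
MRNA_EXON_OFFSETS <- list(c(0L, 299L), c(1500L, 1799L), c(3000L, 3299L))

## Deterministic ground-truth plan shared by all generator stages:
## which lncRNAs belong to which planted module, which are coding
## contaminants, and which positional class each locus realizes.
planGroundTruth <- function(design) {
    stopifnot(validObject(design))
    nL <- design@nLncrna; nM <- design@nMrna
    lncIds <- sprintf("LNC_%06d", seq_len(nL))
    mrnaIds <- sprintf("MRNA_%06d", seq_len(nM))
    ## largest-remainder apportionment gives exact class counts
    raw <- design@lncClassProps * nL
    cnt <- floor(raw)
    rem <- nL - sum(cnt)
    if (rem > 0) {
        ord <- order(raw - cnt, decreasing = TRUE)
        cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
    }
    classes <- rep(c("lincRNA", "antisense_lncRNA", "intronic_lncRNA"),
                   times = cnt)
    moduleOf <- stats::setNames(rep("background", nL + nM),
                                c(lncIds, mrnaIds))
    iL <- 1L; iM <- 1L
    for (pm in design@plantedModules) {
        moduleOf[lncIds[seq.int(iL, iL + pm@size - 1L)]] <- pm@label
        moduleOf[mrnaIds[seq.int(iM, iM + pm@nMrna - 1L)]] <- pm@label
        iL <- iL + pm@size; iM <- iM + pm@nMrna
    }
    set.seed(deriveSeed(design@seed, 11L))
    bg <- lncIds[moduleOf[lncIds] == "background"]
    nContam <- round(design@contaminantFraction * nL)
    if (nContam > length(bg))
        stop("contaminant fraction exceeds the background lncRNA pool")
    contaminants <- sort(sample(bg, nContam))
    list(lncIds = lncIds, mrnaIds = mrnaIds,
         lncClass = stats::setNames(classes, lncIds),
         moduleOf = moduleOf, contaminants = contaminants)
}

#' Generate synthetic annotation and sequences
#'
#' Builds a compact linear genome (one chromosome per 1000 features) of
#' 3-exon coding genes on a regular backbone, then plants 2-exon lncRNA
#' loci so that each realizes its assigned positional class exactly:
#' lincRNAs in intergenic gaps, antisense loci overlapping a host exon on
#' the opposite strand, intronic loci fully inside a host intron.
#' Transcript sequences are random nucleotides of exon-chain length; coding
#' transcripts get a long in-frame ORF injected, lncRNAs do not.
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @param truth optional precomputed plan (internal reuse).
#' @return list: \code{annotation} (\linkS4class{TranscriptAnnotation}),
#'   \code{sequences} (\code{DNAStringSet}), \code{truth} (ground-truth
#'   plan).
#' @export
simulateAnnotation <- function(design, truth = planGroundTruth(design)) {
    nM <- design@nMrna; nL <- design@nLncrna
    if (nM < 1L || nL < 1L) stop("feature counts must be positive")
    nChrom <- max(1L, ceiling((nM + nL) / 1000))
    chromOf <- ((seq_len(nM) - 1L) %% nChrom) + 1L
    posOnChrom <- stats::ave(seq_len(nM), chromOf, FUN = seq_along)
    geneStart <- (posOnChrom - 1L) * GENE_SPACING + 1L
    strand <- ifelse(seq_len(nM) %% 2L == 0L, "-", "+")

    mEx <- do.call(rbind, lapply(seq_len(nM), function(i) {
        off <- do.call(rbind, MRNA_EXON_OFFSETS)
        data.frame(chrom = paste0("chr", chromOf[i]),
                   start = geneStart[i] + off[, 1],
                   end = geneStart[i] + off[, 2],
                   strand = strand[i],
                   transcript_id = truth$mrnaIds[i],
                   gene_id = sprintf("GENE_%06d", i),
                   biotype = "mRNA")
    }))

    ## each lncRNA is placed relative to a host coding gene; hosts cycle
    ## so that at the default scale every host carries at most one locus
    host <- ((seq_len(nL) - 1L) %% nM) + 1L
    round <- (seq_len(nL) - 1L) %/% nM
    lEx <- do.call(rbind, lapply(seq_len(nL), function(k) {
        h <- host[k]; gs <- geneStart[h]
        cls <- truth$lncClass[k]
        shift <- round[k] * 700L
        if (cls == "lincRNA") {
            st <- c(gs + 5000L + shift, gs + 5400L + shift)
            en <- st + c(199L, 199L)
            sd <- "+"
        } else if (cls == "antisense_lncRNA") {
            st <- c(gs + 150L, gs + 600L)
            en <- st + c(199L, 199L)
            sd <- if (strand[h] == "+") "-" else "+"
        } else {
            st <- c(gs + 400L, gs + 700L)
            en <- st + c(149L, 149L)
            sd <- strand[h]
        }
        data.frame(chrom = paste0("chr", chromOf[h]), start = st, end = en,
                   strand = sd, transcript_id = truth$lncIds[k],
                   gene_id = sprintf("LNCG_%06d", k),
                   biotype = "lncRNA_candidate")
    }))
    annot <- makeAnnotation(rbind(mEx, lEx))

    set.seed(deriveSeed(design@seed, 12L))
    lens <- stats::setNames(sum(GenomicRanges::width(annot@exons)),
                            names(annot@exons))
    seqs <- vapply(names(lens), function(id) {
        L <- lens[[id]]
        s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
        if (startsWith(id, "MRNA")) {
            ## inject an ORF covering ~60% of the transcript
            nc <- max(2L, floor(0.6 * L / 3) - 1L)
            body <- replicate(nc - 1L, {
                repeat {
                    cd <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
                    if (!paste(cd, collapse = "") %in%
                        c("TAA", "TAG", "TGA")) return(cd)
                }
            })
            orf <- c("A", "T", "G", as.vector(body), "T", "A", "A")
            s[seq_along(orf)] <- orf
        }
        paste(s, collapse = "")
    }, character(1))
    sequences <- Biostrings::DNAStringSet(seqs)
    names(sequences) <- names(lens)
    list(annotation = attachSequences(annot, sequences),
         sequences = sequences, truth = truth)
}

## Per-sample step profile of a planted module: delta in high stages, 0
## elsewhere.
moduleProfile <- function(pm, stage) {
    ifelse(as.character(stage) %in% pm@highStages, pm@delta, 0)
}

#' Generate synthetic FPKM expression
#'
#' On the log2(FPKM+1) scale each feature is \code{baseline + lambda * E_s
#' + eps} where \code{E_s} is its module's step profile (0 for background
#' features), \code{lambda} is a per-feature loading drawn uniformly from
#' the design's loading range and \code{eps} is Normal(0, noiseSd^2).
#' Values are back-transformed to FPKM = 2^x - 1, floored at 0, so that
#' planted correlations survive the pipeline's own log transform.
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @param truth optional precomputed plan (internal reuse).
#' @return a \linkS4class{StageExpression} over all transcripts.
#' @export
simulateExpression <- function(design, truth = planGroundTruth(design)) {
    stages <- design@stages; reps <- design@replicatesPerStage
    stage <- rep(stages, each = reps)
    sampleIds <- paste0(stage, "_r", rep(seq_len(reps), length(stages)))
    ids <- c(truth$lncIds, truth$mrnaIds)
    n <- length(ids); p <- length(stage)
    set.seed(deriveSeed(design@seed, 13L))
    baseline <- stats::runif(n, design@baselineRange[1],
                             design@baselineRange[2])
    lambda <- stats::runif(n, design@loadingRange[1],
                           design@loadingRange[2])
    x <- matrix(stats::rnorm(n * p, 0, design@noiseSd), n, p,
                dimnames = list(ids, sampleIds))
    x <- x + baseline
    for (pm in design@plantedModules) {
        members <- ids[truth$moduleOf[ids] == pm@label]
        prof <- moduleProfile(pm, stage)
        x[members, ] <- x[members, ] +
            outer(lambda[match(members, ids)], prof)
    }
    v <- pmax(2^x - 1, 0)
    StageExpression(v, stage, stageLevels = stages)
}

#' Generate side tables: verdicts, homology hits, scores, term map
#'
#' Coding-potential verdicts mark the planted contaminants as coding by at
#' least one predictor and everything else as non-coding by all three.
#' Homology hits are drawn per species with species-specific E-value
#' distributions straddling both the loose (1e-3) and strict (1e-10)
#' thresholds; conservation scores are uniform on [0, 1]; the term map
#' contains one term per planted module consisting exactly of its mRNA
#' member genes, plus random background terms.
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @param truth optional precomputed plan (internal reuse).
#' @param matchedFractions named per-species fractions of lncRNAs with at
#'   least one homology hit.
#' @param nBackgroundTerms number of random terms in the term map.
#' @return list: \code{verdicts}, \code{hits}, \code{scores},
#'   \code{term2genes} data.frames and \code{enrichedTerm} (module ->
#'   term id).
#' @export
simulateSideTables <- function(design, truth = planGroundTruth(design),
                               matchedFractions = c(human = 0.44,
                                                    cow = 0.26,
                                                    mouse = 0.25),
                               nBackgroundTerms = 25L) {
    set.seed(deriveSeed(design@seed, 14L))
    lncIds <- truth$lncIds
    contam <- lncIds %in% truth$contaminants
    flags <- matrix(0L, length(lncIds), 3,
                    dimnames = list(lncIds,
                                    c("cpc_coding", "cnci_coding",
                                      "pfam_hit")))
    if (any(contam)) {
        f <- matrix(stats::rbinom(sum(contam) * 3, 1, 0.6), ncol = 3)
        f[rowSums(f) == 0L, 1] <- 1L   # a contaminant trips >= 1 predictor
        flags[contam, ] <- f
    }
    verdicts <- data.frame(transcript_id = lncIds, flags,
                           row.names = NULL, check.names = FALSE)

    ## E-value windows (log10) differ per species so strict-threshold
    ## retention differs: the Fisher stringency contrast has real signal
    evWindow <- list(human = c(-15, -4), cow = c(-12, -2),
                     mouse = c(-11, -1))
    hits <- do.call(rbind, lapply(names(matchedFractions), function(sp) {
        matched <- sample(lncIds,
                          round(matchedFractions[[sp]] * length(lncIds)))
        do.call(rbind, lapply(matched, function(q) {
            nh <- sample(1:3, 1)
            w <- evWindow[[sp]]
            data.frame(query = q,
                       subject = sprintf("%s_lnc_%05d", sp,
                                         sample.int(99999L, nh)),
                       species = sp,
                       evalue = 10^stats::runif(nh, w[1], w[2]),
                       bitscore = round(stats::runif(nh, 40, 400), 1))
        }))
    }))
    rownames(hits) <- NULL

    scores <- data.frame(lncrna_id = lncIds,
                         score = stats::runif(length(lncIds)))

    mrnaGene <- stats::setNames(
        sprintf("GENE_%06d", seq_along(truth$mrnaIds)), truth$mrnaIds)
    t2g <- list(); enrichedTerm <- character()
    for (pm in design@plantedModules) {
        term <- paste0("TERM_", pm@label)
        members <- truth$mrnaIds[truth$moduleOf[truth$mrnaIds] == pm@label]
        t2g[[term]] <- unname(mrnaGene[members])
        enrichedTerm[pm@label] <- term
    }
    for (i in seq_len(nBackgroundTerms)) {
        term <- sprintf("T%04d", i)
        t2g[[term]] <- unname(sample(mrnaGene, sample(15:40, 1)))
    }
    term2genes <- do.call(rbind, lapply(names(t2g), function(tm)
        data.frame(term_id = tm, gene_id = t2g[[tm]],
                   term_name = paste0("synthetic term ", tm))))
    list(verdicts = verdicts, hits = hits, scores = scores,
         term2genes = term2genes, enrichedTerm = enrichedTerm)
}

#' Generate (and optionally write) a full fixture bundle
#'
#' Runs all generator stages under seeds derived from the design seed and
#' returns annotation, sequences, expression, side tables and the
#' ground-truth manifest.  With \code{outdir} set, everything is written in
#' the pipeline's plain-text interchange formats (GTF, FASTA, TSV, JSON
#' manifest).
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @param outdir optional output directory.
#' @return the bundle, a named list; \code{$truth} holds ground truth.
#' @examples
#' b <- simulateBundle(simulationDesign(nMrna = 100, nLncrna = 30,
#'          plantedModules = list(), seed = 7))
#' b$annotation
#' @export
simulateBundle <- function(design, outdir = NULL) {
    truth <- planGroundTruth(design)
    ann <- simulateAnnotation(design, truth)
    se <- simulateExpression(design, truth)
    side <- simulateSideTables(design, truth)
    manifest <- list(
        seed = design@seed,
        stages = design@stages,
        lncClass = as.list(truth$lncClass),
        moduleOf = as.list(truth$moduleOf),
        contaminants = truth$contaminants,
        enrichedTerm = as.list(side$enrichedTerm))
    bundle <- list(design = design, annotation = ann$annotation,
                   sequences = ann$sequences, expression = se,
                   verdicts = side$verdicts, hits = side$hits,
                   scores = side$scores, term2genes = side$term2genes,
                   truth = truth, manifest = manifest)
    if (!is.null(outdir)) {
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        p <- function(f) file.path(outdir, f)
        writeGtf(ann$annotation, p("annotation.gtf"))
        Biostrings::writeXStringSet(ann$sequences, p("transcripts.fa"))
        ev <- fpkm(se)
        writeTsv(data.frame(feature_id = rownames(ev), ev,
                            check.names = FALSE), p("expression.tsv"))
        cd <- SummarizedExperiment::colData(se)
        writeTsv(data.frame(sample = rownames(cd),
                            stage = as.character(cd$stage),
                            replicate = cd$replicate), p("samples.tsv"))
        writeTsv(side$verdicts, p("verdicts.tsv"))
        writeTsv(side$hits, p("homology_hits.tsv"))
        writeTsv(side$scores, p("conservation_scores.tsv"))
        writeTsv(side$term2genes, p("term2gene.tsv"))
        jsonlite::write_json(manifest, p("ground_truth.json"),
                             auto_unbox = TRUE, digits = NA)
        bundle$paths <- stats::setNames(
            file.path(outdir, c("annotation.gtf", "transcripts.fa",
                                "expression.tsv", "samples.tsv",
                                "verdicts.tsv", "homology_hits.tsv",
                                "conservation_scores.tsv", "term2gene.tsv",
                                "ground_truth.json")),
            c("gtf", "fasta", "expression", "samples", "verdicts", "hits",
              "scores", "term2genes", "manifest"))
    }
    bundle
}

#' Readers for the pipeline's tabular interchange formats
#'
#' @param path a TSV file in the corresponding format.
#' @return a data.frame (or \linkS4class{StageExpression} for
#'   \code{readExpressionTsv}).
#' @name readers
NULL

#' @rdname readers
#' @export
readCodingVerdicts <- function(path) {
    df <- readTsv(path)
    need <- c("transcript_id", "cpc_coding", "cnci_coding", "pfam_hit")
    if (!all(need %in% colnames(df)))
        stop("verdict table must have columns: ",
             paste(need, collapse = ", "))
    df
}

#' @rdname readers
#' @export
readHomologyHits <- function(path) {
    df <- readTsv(path)
    need <- c("query", "subject", "species", "evalue", "bitscore")
    if (!all(need %in% colnames(df)))
        stop("hit table must have columns: ", paste(need, collapse = ", "))
    if (any(df$evalue < 0)) stop("negative E-value")
    df
}

#' @rdname readers
#' @export
readConservationScores <- function(path) {
    df <- readTsv(path)
    if (!all(c("lncrna_id", "score") %in% colnames(df)))
        stop("score table must have columns lncrna_id, score")
    df
}

#' @rdname readers
#' @export
readTerm2Genes <- function(path) {
    df <- readTsv(path)
    if (!all(c("term_id", "gene_id") %in% colnames(df)))
        stop("term map must have columns term_id, gene_id")
    df
}

#' @param exprPath,samplePath expression matrix TSV (first column
#'   \code{feature_id}) and sample sheet TSV (\code{sample}, \code{stage},
#'   \code{replicate}).
#' @param stageLevels ordered stage levels.
#' @rdname readers
#' @export
readExpressionTsv <- function(exprPath, samplePath,
                              stageLevels = DEFAULT_STAGES) {
    ev <- readTsv(exprPath)
    ss <- readTsv(samplePath)
    m <- as.matrix(ev[, -1, drop = FALSE])
    rownames(m) <- ev[[1]]
    if (!all(colnames(m) %in% ss$sample))
        stop("sample sheet does not cover all expression columns")
    ss <- ss[match(colnames(m), ss$sample), ]
    StageExpression(m, ss$stage, ss$replicate, stageLevels = stageLevels)
}
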