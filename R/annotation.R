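#' @importFrom GenomicRanges GRanges GRangesList findOverlaps strand seqnames
#'   start end width mcols mcols<- reduce
#' @importFrom IRanges IRanges
NULL

## Internal constructor: build a TranscriptAnnotation from an exon table.
## exonDf: chrom, start, end, strand, transcript_id, gene_id, biotype.
makeAnnotation <- function(exonDf, geneDf = NULL) {
    ord <- order(exonDf$transcript_id, exonDf$start)
    exonDf <- exonDf[ord, , drop = FALSE]
    gr <- GenomicRanges::GRanges(exonDf$chrom,
                                 IRanges::IRanges(exonDf$start, exonDf$end),
                                 strand = exonDf$strand)
    exons <- GenomicRanges::split(gr, factor(exonDf$transcript_id,
                                   levels = unique(exonDf$transcript_id)))
    ## reject overlapping exons within a transcript
    nred <- S4Vectors::elementNROWS(GenomicRanges::reduce(exons))
    nraw <- S4Vectors::elementNROWS(exons)
    if (any(nred != nraw))
        stop("overlapping exons in transcript(s): ",
             paste(utils::head(names(exons)[nred != nraw], 5),
                   collapse = ", "))
    first <- !duplicated(exonDf$transcript_id)
    txMeta <- S4Vectors::DataFrame(
        transcript_id = exonDf$transcript_id[first],
        gene_id = exonDf$gene_id[first],
        biotype = exonDf$biotype[first])
    if (is.null(geneDf)) {
        spans <- unlist(range(exons))
        gdf <- data.frame(gene_id = txMeta$gene_id,
                          chrom = as.character(GenomicRanges::seqnames(spans)),
                          start = GenomicRanges::start(spans),
                          end = GenomicRanges::end(spans),
                          strand = as.character(GenomicRanges::strand(spans)))
        geneDf <- do.call(rbind, lapply(split(gdf, gdf$gene_id), function(g)
            data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
                       start = min(g$start), end = max(g$end),
                       strand = g$strand[1])))
    }
    genes <- GenomicRanges::GRanges(geneDf$chrom,
                                    IRanges::IRanges(geneDf$start, geneDf$end),
                                    strand = geneDf$strand)
    names(genes) <- geneDf$gene_id
    new("TranscriptAnnotation", exons = exons, txMeta = txMeta,
        genes = genes[order(names(genes))])
}

#' Read a GTF annotation
#'
#' Parses a GTF file (attributes \code{transcript_id}, \code{gene_id},
#' optional \code{gene_biotype}) into a \linkS4class{TranscriptAnnotation}.
#' Exon rows define transcripts; gene spans come from \code{gene} rows when
#' present and are otherwise derived as the range of member exons.
#' Coordinates are 1-based inclusive throughout.
#'
#' @param path path to a GTF file.
#' @return A \linkS4class{TranscriptAnnotation}.
#' @export
readGtf <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    ## cheap structural pre-scan so malformed lines are reported by number
    lines <- readLines(path)
    body <- !startsWith(lines, "#") & nzchar(lines)
    fields <- strsplit(lines[body], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 9L))
        stop("malformed GTF line ", which(body)[nf != 9L][1],
             ": expected 9 tab-separated fields, found ", nf[nf != 9L][1])
    st <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
    en <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
    bad <- which(is.na(st) | is.na(en) | en < st)
    if (length(bad))
        stop("malformed GTF line ", which(body)[bad[1]],
             ": exon end precedes start (or non-numeric coordinates)")
    gr <- rtracklayer::import(path, format = "gtf")
    m <- GenomicRanges::mcols(gr)
    ex <- gr[m$type == "exon"]
    if (!length(ex)) stop("no exon rows in ", path)
    em <- GenomicRanges::mcols(ex)
    if (anyNA(em$transcript_id) || is.null(em$transcript_id))
        stop("exon row missing mandatory attribute transcript_id")
    if (anyNA(em$gene_id) || is.null(em$gene_id))
        stop("exon row missing mandatory attribute gene_id")
    txRows <- gr[m$type == "transcript"]
    if (length(txRows)) {
        dup <- duplicated(GenomicRanges::mcols(txRows)$transcript_id)
        if (any(dup))
            stop("duplicate transcript_id: ",
                 paste(unique(
                     GenomicRanges::mcols(txRows)$transcript_id[dup]),
                     collapse = ", "))
    }
    biotype <- em$gene_biotype
    if (is.null(biotype)) biotype <- rep(NA_character_, length(ex))
    exonDf <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(ex)),
        start = GenomicRanges::start(ex), end = GenomicRanges::end(ex),
        strand = as.character(GenomicRanges::strand(ex)),
        transcript_id = em$transcript_id, gene_id = em$gene_id,
        biotype = ifelse(is.na(biotype), "mRNA", biotype))
    geneRows <- gr[m$type == "gene"]
    geneDf <- NULL
    if (length(geneRows))
        geneDf <- data.frame(
            gene_id = GenomicRanges::mcols(geneRows)$gene_id,
            chrom = as.character(GenomicRanges::seqnames(geneRows)),
            start = GenomicRanges::start(geneRows),
            end = GenomicRanges::end(geneRows),
            strand = as.character(GenomicRanges::strand(geneRows)))
    makeAnnotation(exonDf, geneDf)
}

#' Write a GTF annotation
#'
#' Emits gene, transcript and exon rows with \code{gene_id},
#' \code{transcript_id} and \code{gene_biotype} attributes, readable back
#' by \code{\link{readGtf}} with identical exon chains.
#'
#' @param annot a \linkS4class{TranscriptAnnotation}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGtf <- function(annot, path) {
    exons <- annot@exons
    meta <- annot@txMeta
    spans <- unlist(range(exons))
    txGr <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(spans),
        IRanges::IRanges(GenomicRanges::start(spans),
                         GenomicRanges::end(spans)),
        strand = GenomicRanges::strand(spans),
        type = "transcript", gene_id = meta$gene_id,
        transcript_id = meta$transcript_id, gene_biotype = meta$biotype)
    flat <- unlist(exons)
    idx <- rep(seq_along(exons), S4Vectors::elementNROWS(exons))
    exGr <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(flat),
        IRanges::IRanges(GenomicRanges::start(flat),
                         GenomicRanges::end(flat)),
        strand = GenomicRanges::strand(flat),
        type = "exon", gene_id = meta$gene_id[idx],
        transcript_id = meta$transcript_id[idx],
        gene_biotype = meta$biotype[idx])
    g <- annot@genes
    gBio <- meta$biotype[match(names(g), meta$gene_id)]
    gGr <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(g),
        IRanges::IRanges(GenomicRanges::start(g), GenomicRanges::end(g)),
        strand = GenomicRanges::strand(g),
        type = "gene", gene_id = names(g),
        transcript_id = NA_character_, gene_biotype = gBio)
    all <- c(gGr, txGr, exGr)
    all <- all[order(as.character(GenomicRanges::seqnames(all)),
                     GenomicRanges::start(all))]
    rtracklayer::export(all, path, format = "gtf")
    invisible(path)
}

#' Transcript lengths and exon counts
#'
#' @param annot a \linkS4class{TranscriptAnnotation}.
#' @return data.frame: transcript_id, gene_id, biotype, n_exons, length.
#' @export
transcriptStats <- function(annot) {
    data.frame(transcript_id = annot@txMeta$transcript_id,
               gene_id = annot@txMeta$gene_id,
               biotype = annot@txMeta$biotype,
               n_exons = S4Vectors::elementNROWS(annot@exons),
               length = sum(GenomicRanges::width(annot@exons)))
}

#' Longest open reading frame
#'
#' Scans the three forward frames of a sense-orientation transcript
#' sequence for the longest ATG..stop ORF.  The length counts from the A of
#' the ATG through the last base of the stop codon (TAA/TAG/TGA), so the
#' minimal complete ORF \code{ATGTAA} has length 6.  A complete stop is
#' required: an unterminated ATG contributes nothing.  ORFs containing an N
#' are skipped.
#'
#' @param sequence a nucleotide string over A, C, G, T, N (case
#'   insensitive).
#' @return integer ORF length in nt; 0 when no complete ORF exists.
#' @examples
#' longestOrfLength("ATGTAA")        # 6
#' longestOrfLength("ATGAAA")        # 0, no stop
#' @export
longestOrfLength <- function(sequence) {
    s <- toupper(as.character(sequence))
    L <- nchar(s)
    if (L < 6L) return(0L)
    if (grepl("[^ACGTN]", s)) stop("sequence must be over A,C,G,T,N")
    best <- 0L
    stops <- c("TAA", "TAG", "TGA")
    for (frame in 0:2) {
        n <- (L - frame) %/% 3L
        if (n < 2L) next
        at <- frame + 3L * (seq_len(n) - 1L) + 1L
        codons <- substring(s, at, at + 2L)
        valid <- !grepl("N", codons, fixed = TRUE)
        seg <- cumsum(!valid)          # codons sharing a segment have no N
        isStart <- codons == "ATG"
        isStop <- codons %in% stops
        stopIdx <- which(isStop)
        if (!length(stopIdx)) next
        for (i in which(isStart)) {
            j <- stopIdx[stopIdx >= i + 1L]
            if (!length(j)) next
            j <- j[1L]
            if (seg[j] != seg[i]) next  # an N interrupts this ORF
            len <- (j - i + 1L) * 3L
            if (len > best) best <- len
        }
    }
    best
}

#' Positional classification of lncRNA candidates
#'
#' Assigns each lncRNA candidate one of three positional classes with a
#' fixed precedence: \code{antisense_lncRNA} when any lncRNA exon overlaps
#' an mRNA exon on the opposite strand; otherwise \code{intronic_lncRNA}
#' when the lncRNA span lies fully inside a coding-gene span with zero
#' same-strand exon overlap; otherwise \code{lincRNA}.  With no coding
#' genes every candidate is a lincRNA.
#'
#' @param annot a \linkS4class{TranscriptAnnotation} containing both the
#'   candidates and the coding (mRNA) models.
#' @param lncIds transcript ids to classify; defaults to all transcripts
#'   whose biotype is not \code{mRNA}.
#' @return named character vector of classes, one per candidate.
#' @export
classifyLncrnaPosition <- function(annot, lncIds = NULL) {
    meta <- annot@txMeta
    if (is.null(lncIds)) lncIds <- meta$transcript_id[meta$biotype != "mRNA"]
    if (!all(lncIds %in% meta$transcript_id))
        stop("unknown transcript id(s)")
    cls <- stats::setNames(rep("lincRNA", length(lncIds)), lncIds)
    mrnaTx <- meta$transcript_id[meta$biotype == "mRNA"]
    if (!length(mrnaTx) || !length(lncIds)) return(cls)
    mrnaEx <- unlist(annot@exons[mrnaTx], use.names = FALSE)
    lncExons <- annot@exons[lncIds]
    flat <- unlist(lncExons, use.names = FALSE)
    who <- rep(seq_along(lncIds), S4Vectors::elementNROWS(lncExons))
    ## antisense: exon-level overlap on the opposite strand
    hits <- GenomicRanges::findOverlaps(flat, mrnaEx, ignore.strand = TRUE)
    opp <- as.character(GenomicRanges::strand(flat))[S4Vectors::queryHits(hits)] !=
        as.character(GenomicRanges::strand(mrnaEx))[S4Vectors::subjectHits(hits)]
    cls[unique(who[S4Vectors::queryHits(hits)[opp]])] <- "antisense_lncRNA"
    ## intronic: span within a coding gene span, no same-strand exon overlap
    mrnaGenes <- unique(meta$gene_id[meta$biotype == "mRNA"])
    gspan <- annot@genes[names(annot@genes) %in% mrnaGenes]
    spans <- unlist(range(lncExons))
    within <- GenomicRanges::findOverlaps(spans, gspan, type = "within",
                                          ignore.strand = TRUE)
    sameStrand <- GenomicRanges::findOverlaps(flat, mrnaEx,
                                              ignore.strand = TRUE)
    same <- as.character(GenomicRanges::strand(flat))[S4Vectors::queryHits(sameStrand)] ==
        as.character(GenomicRanges::strand(mrnaEx))[S4Vectors::subjectHits(sameStrand)]
    hasSameOv <- unique(who[S4Vectors::queryHits(sameStrand)[same]])
    insideIdx <- unique(S4Vectors::queryHits(within))
    for (i in insideIdx)
        if (cls[i] == "lincRNA" && !(i %in% hasSameOv))
            cls[i] <- "intronic_lncRNA"
    cls
}

#' Structural summary per biotype
#'
#' Per-biotype distributions of exon count, transcript length and longest
#' ORF length.  ORF lengths require sequences (see
#' \code{\link{attachSequences}}); without them the ORF column is NA.
#'
#' @param annot a \linkS4class{TranscriptAnnotation}.
#' @return list with \code{perTranscript} (one row per transcript) and
#'   \code{medians} (one row per biotype).
#' @export
structureSummary <- function(annot) {
    tab <- transcriptStats(annot)
    if (!nrow(tab))
        return(list(perTranscript = tab, medians = data.frame()))
    seqs <- annot@txMeta$sequence
    tab$orf_length <- if (is.null(seqs)) NA_real_ else
        vapply(seqs, function(s)
            if (is.na(s)) NA_real_ else as.numeric(longestOrfLength(s)),
            numeric(1), USE.NAMES = FALSE)
    med <- do.call(rbind, lapply(split(tab, tab$biotype), function(g)
        data.frame(biotype = g$biotype[1], n = nrow(g),
                   median_exons = stats::median(g$n_exons),
                   median_length = stats::median(g$length),
                   median_orf = stats::median(g$orf_length))))
    rownames(med) <- NULL
    list(perTranscript = tab, medians = med)
}

#' Attach transcript sequences
#'
#' @param annot a \linkS4class{TranscriptAnnotation}.
#' @param seqs a named \code{DNAStringSet} (or named character vector)
#'   keyed by transcript id.
#' @return the annotation with a \code{sequence} metadata column; errors
#'   if a sequence length disagrees with the exon-chain length.
#' @export
attachSequences <- function(annot, seqs) {
    s <- stats::setNames(as.character(seqs), names(seqs))
    ids <- annot@txMeta$transcript_id
    seqv <- s[ids]
    have <- !is.na(seqv)
    lens <- sum(GenomicRanges::width(annot@exons))
    bad <- have & nchar(seqv) != lens
    if (any(bad))
        stop("sequence length mismatch for: ",
             paste(utils::head(ids[bad], 5), collapse = ", "))
    annot@txMeta$sequence <- unname(seqv)
    annot
}

#' Gene-level FPKM
#'
#' Sums transcript FPKMs within each gene group, per sample; the standard
#' transcript-to-gene roll-up for assembled transcriptomes.  Gene rows are
#' ordered lexicographically.
#'
#' @param se a \linkS4class{StageExpression} whose features are transcript
#'   ids.
#' @param annot a \linkS4class{TranscriptAnnotation} mapping transcripts to
#'   genes.
#' @return a \linkS4class{StageExpression} over genes.
#' @export
geneLevelFpkm <- function(se, annot) {
    v <- fpkm(se)
    map <- stats::setNames(annot@txMeta$gene_id, annot@txMeta$transcript_id)
    g <- map[rownames(v)]
    if (anyNA(g))
        stop("transcript(s) without gene_id: ",
             paste(utils::head(rownames(v)[is.na(g)], 5), collapse = ", "))
    out <- rowsum(v, group = g, reorder = TRUE)
    cd <- SummarizedExperiment::colData(se)
    StageExpression(out, as.character(cd$stage), cd$replicate,
                    stageLevels = levels(cd$stage))
}
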