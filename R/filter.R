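#' lncRNA identification cascade
#'
#' Applies the structural and coding-potential filters to candidate
#' transcripts.  A candidate is retained iff its exon-chain length is
#' strictly greater than \code{minLengthNt} (the "> 200 nt" definition of a
#' lncRNA), it has at least \code{minExons} exons (multi-exonic), and all
#' three coding-potential predictors call it non-coding (no CPC coding
#' call, no CNCI coding call, no Pfam domain hit).  Drop counts partition
#' the input by the first failing stage, in the order length, exons,
#' coding consensus.
#'
#' @param annot a \linkS4class{TranscriptAnnotation} of candidates (only
#'   non-mRNA biotypes are evaluated).
#' @param verdicts data.frame with columns \code{transcript_id},
#'   \code{cpc_coding}, \code{cnci_coding}, \code{pfam_hit} (0/1 or
#'   logical); a verdict is required for every structurally retained
#'   candidate.
#' @param config a \linkS4class{PipelineConfig}.
#' @return list: \code{retained} (transcript ids), \code{drops} (named
#'   counts: short, few_exons, coding), \code{table} (per-candidate
#'   decisions).
#' @export
applyIdentificationFilter <- function(annot, verdicts,
                                      config = pipelineConfig()) {
    ts <- transcriptStats(annot)
    cand <- ts[ts$biotype != "mRNA", , drop = FALSE]
    longEnough <- cand$length > config@minLengthNt
    multiExon <- cand$n_exons >= config@minExons
    structural <- longEnough & multiExon
    idx <- match(cand$transcript_id, verdicts$transcript_id)
    missing <- structural & is.na(idx)
    if (any(missing))
        stop("no coding verdict for structurally retained transcript(s): ",
             paste(utils::head(cand$transcript_id[missing], 5),
                   collapse = ", "))
    coding <- with(verdicts[idx, , drop = FALSE],
                   as.logical(cpc_coding) | as.logical(cnci_coding) |
                   as.logical(pfam_hit))
    keep <- structural & !coding
    keep[is.na(keep)] <- FALSE
    table <- data.frame(transcript_id = cand$transcript_id,
                        length = cand$length, n_exons = cand$n_exons,
                        long_enough = longEnough, multi_exon = multiExon,
                        noncoding_consensus = structural & !coding,
                        retained = keep)
    drops <- c(short = sum(!longEnough),
               few_exons = sum(longEnough & !multiExon),
               coding = sum(structural & coding, na.rm = TRUE))
    list(retained = cand$transcript_id[keep], drops = drops, table = table)
}

#' Venn breakdown of the three non-coding predicates
#'
#' Counts the 7 non-empty regions of the three-way Venn diagram over the
#' predicates "called non-coding by CPC", "by CNCI", and "no Pfam hit".
#' The triple intersection is the coding-consensus pass set.
#'
#' @param verdicts verdict data.frame (see
#'   \code{\link{applyIdentificationFilter}}).
#' @return named integer vector over the 7 regions (\code{cpc},
#'   \code{cnci}, \code{pfam}, \code{cpc.cnci}, \code{cpc.pfam},
#'   \code{cnci.pfam}, \code{cpc.cnci.pfam}) plus \code{none}; regions are
#'   disjoint and sum to the input size.
#' @export
vennCodingPotential <- function(verdicts) {
    a <- !as.logical(verdicts$cpc_coding)   # non-coding by CPC
    b <- !as.logical(verdicts$cnci_coding)  # non-coding by CNCI
    c_ <- !as.logical(verdicts$pfam_hit)    # no Pfam domain
    key <- paste0(ifelse(a, "1", "0"), ifelse(b, "1", "0"),
                  ifelse(c_, "1", "0"))
    cnt <- function(k) sum(key == k)
    out <- c(cpc = cnt("100"), cnci = cnt("010"), pfam = cnt("001"),
             cpc.cnci = cnt("110"), cpc.pfam = cnt("101"),
             cnci.pfam = cnt("011"), cpc.cnci.pfam = cnt("111"),
             none = cnt("000"))
    stopifnot(sum(out) == nrow(verdicts))
    out
}

#' Positional-class composition of retained lncRNAs
#'
#' @param classes character vector of positional classes (from
#'   \code{\link{classifyLncrnaPosition}}).
#' @return data.frame: class, count, proportion (sums to 1).
#' @export
typeComposition <- function(classes) {
    if (!length(classes))
        return(data.frame(class = character(), count = integer(),
                          proportion = numeric()))
    tab <- table(classes)
    data.frame(class = names(tab), count = as.integer(tab),
               proportion = as.numeric(tab) / length(classes),
               row.names = NULL)
}
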