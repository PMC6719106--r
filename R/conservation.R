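#' Queries matched at an E-value threshold
#'
#' A query counts as matched when at least one of its hits has E-value
#' strictly below the threshold; multiple hits collapse to one matched
#' lncRNA (counts are per lncRNA, not per hit).
#'
#' @param hits data.frame with columns \code{query} and \code{evalue}
#'   (see \code{\link{readHomologyHits}}).
#' @param threshold positive E-value cut, exclusive.
#' @return sorted character vector of matched query ids.
#' @export
filterHitsByEvalue <- function(hits, threshold) {
    stopifnot(threshold > 0)
    if (!nrow(hits)) return(character())
    sort(unique(hits$query[hits$evalue < threshold]))
}

#' Matched percentage
#'
#' Reports \code{100 * matched / total} both raw and rounded to two
#' decimals with half-up rounding, the convention used for published
#' cross-species sharing percentages (e.g. 6649 of 15079 is 44.09).
#'
#' @param total,matched non-negative counts, \code{matched <= total},
#'   \code{total > 0}.
#' @return list: \code{raw}, \code{percent} (2 dp), \code{percentInt}
#'   (integer, half-up).
#' @export
matchedFraction <- function(total, matched) {
    if (total <= 0) stop("total must be positive")
    if (matched < 0 || matched > total)
        stop("matched must lie in [0, total]")
    raw <- 100 * matched / total
    list(raw = raw, percent = roundHalfUp(raw, 2),
         percentInt = roundHalfUp(raw, 0))
}

#' Reciprocally matched queries
#'
#' A query is retained when it passes the E-value filter in the forward
#' direction and also appears as the subject of a passing hit in the
#' reverse direction (two-way alignment).
#'
#' @param hitsAb forward hit table (query = this dataset's ids).
#' @param hitsBa reverse hit table (subject = this dataset's ids).
#' @param threshold exclusive E-value cut applied in both directions.
#' @return sorted character vector of reciprocally matched ids.
#' @export
reciprocalMatch <- function(hitsAb, hitsBa, threshold) {
    fwd <- filterHitsByEvalue(hitsAb, threshold)
    rev <- if (nrow(hitsBa))
        unique(hitsBa$subject[hitsBa$evalue < threshold]) else character()
    sort(intersect(fwd, rev))
}

#' Conservation-score filter
#'
#' Retains lncRNAs whose conservation score strictly exceeds the cut
#' ("score above 0.8" semantics: a score of exactly 0.8 is excluded).
#'
#' @param scores data.frame with \code{lncrna_id} and \code{score} in
#'   [0, 1].
#' @param minScore exclusive lower cut.
#' @return sorted character vector of retained ids.
#' @export
filterByScore <- function(scores, minScore = 0.8) {
    if (any(scores$score < 0 | scores$score > 1))
        stop("conservation scores must lie in [0, 1]")
    sort(scores$lncrna_id[scores$score > minScore])
}

#' Loose-vs-strict stringency contrast (Fisher's exact test)
#'
#' Tests whether a species loses proportionally more matches than the
#' background species when the E-value threshold is tightened from loose
#' to strict.  The 2x2 table has rows {species, background} and columns
#' {retained at strict, lost between loose and strict}; the two-sided p is
#' the exact conditional test summing, over all tables with the observed
#' margins, the hypergeometric point probabilities no larger than the
#' observed one.
#'
#' @param speciesLoose,speciesStrict matched counts for the species of
#'   interest at the loose and strict thresholds.
#' @param bgLoose,bgStrict the same counts for the background species.
#' @return list: \code{table} (the 2x2), \code{p} (two-sided exact p).
#'   Any zero margin gives p = 1 with a warning.
#' @examples
#' stringencyContrast(10, 0, 10, 10)$p   # maximal imbalance
#' @export
stringencyContrast <- function(speciesLoose, speciesStrict, bgLoose,
                               bgStrict) {
    if (speciesStrict > speciesLoose || bgStrict > bgLoose)
        stop("strict counts cannot exceed loose counts")
    if (min(speciesLoose, speciesStrict, bgLoose, bgStrict) < 0)
        stop("counts must be non-negative")
    tab <- matrix(c(speciesStrict, speciesLoose - speciesStrict,
                    bgStrict, bgLoose - bgStrict),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("species", "background"),
                                  c("strict", "lost")))
    list(table = tab, p = fisherTwoSided(tab))
}

## Two-sided Fisher p by exact enumeration over the hypergeometric support
## with the point-probability rule; the relative tolerance guards against
## ties broken by floating-point noise.
fisherTwoSided <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    if (m == 0 || n == 0 || k == 0 || sum(tab[, 2]) == 0) {
        warning("zero margin in 2x2 table; p set to 1")
        return(1.0)
    }
    support <- max(0, k - n):min(k, m)
    d <- stats::dhyper(support, m, n, k)
    obs <- stats::dhyper(tab[1, 1], m, n, k)
    min(1, sum(d[d <= obs * (1 + 1e-7)]))
}
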