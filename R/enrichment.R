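#' Hypergeometric over-representation
#'
#' Upper-tail hypergeometric test of a study gene set against a
#' user-supplied term-to-gene map: for a term annotating K of the N
#' population genes, with k of the n study genes hitting it, p = P(X >= k)
#' for X hypergeometric(N, K, n).  Terms are first intersected with the
#' population; terms with k = 0 get p = 1.  Results are BH-adjusted and
#' sorted by p then term id.
#'
#' @param study character vector of study genes (must be a subset of
#'   \code{population}).
#' @param population character vector, the gene universe.
#' @param term2genes data.frame with \code{term_id}, \code{gene_id} and
#'   optional \code{term_name}.
#' @return data.frame: term_id, term_name, k, K, n, N, p_value, q_value.
#' @examples
#' t2g <- data.frame(term_id = "T1", gene_id = paste0("g", 1:10))
#' hypergeometricEnrichment(paste0("g", 1:10), paste0("g", 1:20), t2g)
#' @export
hypergeometricEnrichment <- function(study, population, term2genes) {
    study <- unique(study); population <- unique(population)
    stray <- setdiff(study, population)
    if (length(stray))
        stop("study genes outside the population: ",
             paste(utils::head(stray, 5), collapse = ", "))
    N <- length(population); n <- length(study)
    terms <- split(term2genes$gene_id, term2genes$term_id)
    nameOf <- if ("term_name" %in% colnames(term2genes))
        tapply(term2genes$term_name, term2genes$term_id, `[`, 1) else NULL
    rows <- lapply(names(terms), function(tm) {
        genes <- intersect(unique(terms[[tm]]), population)
        K <- length(genes)
        k <- length(intersect(genes, study))
        p <- if (k == 0) 1 else
            stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(term_id = tm,
                   term_name = if (is.null(nameOf)) tm else nameOf[[tm]],
                   k = k, K = K, n = n, N = N, p_value = p)
    })
    out <- do.call(rbind, c(rows, make.row.names = FALSE))
    out$q_value <- bhAdjust(out$p_value)
    out[order(out$p_value, out$term_id), , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' a thin validated wrapper over \code{p.adjust(method = "BH")}.
#'
#' @param p numeric p-values in [0, 1].
#' @return q-values, each in [p, 1].
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Top-N enrichment report
#'
#' Convenience slice mirroring the common reporting convention of 10
#' GO-like and 20 pathway-like rows.
#'
#' @param result \code{\link{hypergeometricEnrichment}} output.
#' @param n rows to keep.
#' @return the first \code{n} rows.
#' @export
topTerms <- function(result, n = 10) {
    utils::head(result, n)
}
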