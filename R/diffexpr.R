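#' Pairwise stage-wise differential expression
#'
#' Welch's two-sided t-test on log2(FPKM + 1) between two stages, feature
#' by feature.  The log2 fold change is \code{mean(stage_b) -
#' mean(stage_a)} on that scale; a feature is flagged differentially
#' expressed when p < \code{deAlpha}.  Features with zero variance in both
#' groups and equal means get p = 1; with zero variance and unequal means
#' the difference is infinitely many standard errors away, so p = 0.
#'
#' @param se a \linkS4class{StageExpression}.
#' @param stageA,stageB stage labels, \code{stageA} earlier in stage
#'   order.
#' @param config a \linkS4class{PipelineConfig}.
#' @return data.frame: feature_id, stage_a, stage_b, log2_fc, t, df,
#'   p_value, direction, de.
#' @export
pairwiseDE <- function(se, stageA, stageB, config = pipelineConfig()) {
    st <- stageOf(se)
    if (!all(c(stageA, stageB) %in% levels(st)))
        stop("unknown stage label: ",
             paste(setdiff(c(stageA, stageB), levels(st)), collapse = ", "))
    x <- log2Fpkm(se)
    a <- x[, st == stageA, drop = FALSE]
    b <- x[, st == stageB, drop = FALSE]
    na <- ncol(a); nb <- ncol(b)
    if (na < 2 || nb < 2) stop("each stage needs >= 2 replicates")
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
    seSq <- va / na + vb / nb
    lfc <- mb - ma
    t <- lfc / sqrt(seSq)
    df <- seSq^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(t), df)
    degenerate <- seSq == 0
    p[degenerate & lfc == 0] <- 1
    t[degenerate & lfc == 0] <- 0
    p[degenerate & lfc != 0] <- 0
    data.frame(feature_id = rownames(x), stage_a = stageA,
               stage_b = stageB, log2_fc = lfc, t = t, df = df,
               p_value = p,
               direction = ifelse(lfc >= 0, "up", "down"),
               de = p < config@deAlpha, row.names = NULL)
}

#' Differential expression across all stage pairs
#'
#' Runs \code{\link{pairwiseDE}} over every unordered stage pair (21 pairs
#' for 7 stages) and reports the union of differentially expressed
#' features together with up/down counts per pair, separately flagging the
#' adjacent (consecutive-stage) pairs.
#'
#' @param se a \linkS4class{StageExpression}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param features optional feature subset.
#' @return list: \code{results} (all per-pair tables, named "A_vs_B"),
#'   \code{union} (DE feature ids), \code{pairCounts} (per-pair up/down DE
#'   counts with an \code{adjacent} flag).
#' @export
deUnion <- function(se, config = pipelineConfig(), features = NULL) {
    if (!is.null(features)) se <- se[features, ]
    stages <- levels(stageOf(se))
    pairs <- utils::combn(stages, 2, simplify = FALSE)
    results <- list()
    counts <- list()
    for (pr in pairs) {
        r <- pairwiseDE(se, pr[1], pr[2], config)
        key <- paste0(pr[1], "_vs_", pr[2])
        results[[key]] <- r
        counts[[key]] <- data.frame(
            stage_a = pr[1], stage_b = pr[2],
            adjacent = match(pr[2], stages) - match(pr[1], stages) == 1,
            n_up = sum(r$de & r$direction == "up"),
            n_down = sum(r$de & r$direction == "down"))
    }
    un <- sort(unique(unlist(lapply(results, function(r)
        r$feature_id[r$de]))))
    list(results = results, union = un,
         pairCounts = do.call(rbind, c(counts, make.row.names = FALSE)))
}

#' Stage detection summary
#'
#' A feature counts as detected in a stage when its mean FPKM over that
#' stage's replicates exceeds \code{detectionFpkmMin}.  Reports, for each
#' feature, the set of stages in which it is detected, plus the count and
#' integer percentage (half-up) of features detected in every stage.
#'
#' @param se a \linkS4class{StageExpression}.
#' @param config a \linkS4class{PipelineConfig}.
#' @return list: \code{detected} (logical matrix features x stages),
#'   \code{sharedAll} (ids detected in all stages), \code{nSharedAll},
#'   \code{percentSharedAll} (integer percent).
#' @export
stageDetectionSummary <- function(se, config = pipelineConfig()) {
    v <- fpkm(se)
    st <- stageOf(se)
    stageMeans <- vapply(levels(st), function(s)
        rowMeans(v[, st == s, drop = FALSE]), numeric(nrow(v)))
    detected <- stageMeans > config@detectionFpkmMin
    shared <- rownames(v)[rowSums(detected) == nlevels(st)]
    list(detected = detected, sharedAll = shared,
         nSharedAll = length(shared),
         percentSharedAll = roundHalfUp(100 * length(shared) / nrow(v), 0))
}
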