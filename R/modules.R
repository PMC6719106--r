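## Signed weighted co-expression network, written from scratch:
## Pearson correlation -> soft threshold -> signed adjacency -> topological
## overlap -> average-linkage tree -> static branch cut -> eigengenes ->
## module-stage statistics -> temporal classification.

#' Pearson correlation matrix on log2(FPKM + 1)
#'
#' @param se a \linkS4class{StageExpression} restricted to the features to
#'   be networked (typically the differentially expressed set).
#' @param features optional feature subset.
#' @return symmetric correlation matrix with unit diagonal.  Zero-variance
#'   features are an error: they must be filtered before networking.
#' @export
pearsonMatrix <- function(se, features = NULL) {
    if (!is.null(features)) se <- se[features, ]
    x <- log2Fpkm(se)
    if (ncol(x) < 3) stop("need >= 3 samples")
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0))
        stop("zero-variance feature(s): ",
             paste(utils::head(rownames(x)[sds == 0], 5), collapse = ", "))
    r <- stats::cor(t(x))
    diag(r) <- 1
    r
}

#' Signed adjacency
#'
#' \code{a_ij = ((1 + r_ij) / 2) ^ beta} off the diagonal, so perfectly
#' anti-correlated features get adjacency 0 and the sign of the
#' correlation is preserved in the network; the diagonal is forced to 1.
#'
#' @param cor correlation matrix.
#' @param beta integer soft-threshold power, >= 1.
#' @return adjacency matrix in [0, 1].
#' @export
signedAdjacency <- function(cor, beta) {
    stopifnot(beta >= 1, abs(beta - round(beta)) < 1e-9)
    a <- ((1 + cor) / 2)^beta
    diag(a) <- 1
    a
}

#' Scale-free soft-threshold selection
#'
#' For each candidate power, builds the signed adjacency, computes the
#' connectivity \code{k_i = sum_{j != i} a_ij}, bins log10(k) into
#' \code{nBins} equal-width bins and regresses log10(bin frequency) on
#' log10(bin mean k).  The scale-free fit index is R^2 signed by the
#' negative of the slope (a power-law degree distribution has negative
#' slope).  The chosen beta is the smallest power whose signed R^2 reaches
#' \code{fitTarget}, falling back to the best achieved signed R^2 when
#' none does.
#'
#' @param cor correlation matrix.
#' @param powers candidate integer powers.
#' @param fitTarget signed R^2 target (default 0.8).
#' @param nBins connectivity histogram bins.
#' @param fallbackBeta power used when the connectivity histogram is
#'   degenerate (all-equal k); returned with a warning.
#' @return list: \code{beta}, \code{fitTable} (power, signedR2, slope,
#'   meanK), \code{reachedTarget}.
#' @export
pickSoftThreshold <- function(cor, powers = 1:20, fitTarget = 0.8,
                              nBins = 10, fallbackBeta = 12) {
    rows <- lapply(powers, function(b) {
        a <- signedAdjacency(cor, b)
        k <- rowSums(a) - 1
        if (stats::sd(k) < .Machine$double.eps * max(1, mean(k)))
            return(data.frame(power = b, signedR2 = NA_real_,
                              slope = NA_real_, meanK = mean(k)))
        lk <- log10(pmax(k, .Machine$double.xmin))
        bins <- cut(lk, breaks = nBins)
        freq <- tapply(lk, bins, length)
        mk <- tapply(k, bins, mean)
        keep <- !is.na(freq) & freq > 0
        if (sum(keep) < 3)
            return(data.frame(power = b, signedR2 = NA_real_,
                              slope = NA_real_, meanK = mean(k)))
        fit <- stats::lm(log10(freq[keep]) ~ log10(mk[keep]))
        slope <- stats::coef(fit)[2]
        r2 <- summary(fit)$r.squared
        data.frame(power = b, signedR2 = r2 * sign(-slope), slope = slope,
                   meanK = mean(k))
    })
    fitTable <- do.call(rbind, c(rows, make.row.names = FALSE))
    if (all(is.na(fitTable$signedR2))) {
        warning("degenerate connectivity distribution; falling back to ",
                "beta = ", fallbackBeta)
        return(list(beta = fallbackBeta, fitTable = fitTable,
                    reachedTarget = FALSE))
    }
    ok <- which(!is.na(fitTable$signedR2) &
                fitTable$signedR2 >= fitTarget)
    if (length(ok)) {
        beta <- fitTable$power[ok[1]]
        reached <- TRUE
    } else {
        beta <- fitTable$power[which.max(fitTable$signedR2)]
        reached <- FALSE
    }
    list(beta = beta, fitTable = fitTable, reachedTarget = reached)
}

#' Topological overlap matrix
#'
#' Combines direct adjacency with shared-neighbour support: with
#' \code{k_i = sum_{u != i} a_iu} and
#' \code{l_ij = sum_{u != i,j} a_iu a_uj},
#' \code{TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)}; the
#' diagonal is 1.  For adjacency in [0, 1] the result stays in [0, 1].
#'
#' @param adj adjacency matrix (symmetric, unit diagonal, entries in
#'   [0, 1]).
#' @return the TOM, same dimensions.
#' @export
tomSimilarity <- function(adj) {
    if (!isSymmetric(unname(adj))) stop("adjacency must be symmetric")
    a0 <- adj
    diag(a0) <- 0
    L <- a0 %*% a0          # l_ij: u = i and u = j drop out via zero diag
    k <- rowSums(a0)
    denom <- outer(k, k, pmin) + 1 - a0
    tom <- (L + a0) / denom
    diag(tom) <- 1
    dimnames(tom) <- dimnames(adj)
    tom
}

#' Average-linkage (UPGMA) clustering of a TOM dissimilarity
#'
#' @param diss square symmetric dissimilarity with zero diagonal
#'   (typically \code{1 - tomSimilarity(adj)}).
#' @return an \code{hclust} tree; merge heights are non-decreasing.
#' @export
averageLinkage <- function(diss) {
    if (!isSymmetric(unname(as.matrix(diss))))
        stop("dissimilarity must be symmetric")
    d <- as.matrix(diss)
    if (any(abs(diag(d)) > 1e-12)) stop("dissimilarity diagonal must be 0")
    stats::hclust(stats::as.dist(d), method = "average")
}

#' Static branch cut into modules
#'
#' Cuts the dendrogram at a fixed height (default 0.995 of the maximum
#' merge height); branches with at least \code{minModuleSize} members
#' become modules, labelled by colour aliases in decreasing size order
#' (ties broken by the branch's smallest member index); everything else is
#' \code{grey}.
#'
#' @param dend an \code{hclust} tree from \code{\link{averageLinkage}}.
#' @param minModuleSize minimum branch size (>= 2).
#' @param cutHeight static cut height; default 0.995 * max height.
#' @return list: \code{labels} (named feature -> colour),
#'   \code{moduleOrder} (colours, decreasing size), \code{cutHeight}.
#' @export
treeCutModules <- function(dend, minModuleSize = 20, cutHeight = NULL) {
    if (minModuleSize < 2) stop("minModuleSize must be >= 2")
    if (is.null(cutHeight)) cutHeight <- 0.995 * max(dend$height)
    ## UPGMA heights are non-decreasing in exact arithmetic, but exactly
    ## tied merges can come back microscopically out of order; enforce
    ## monotonicity so cutree accepts the tree
    viol <- diff(dend$height)
    if (any(viol < 0)) {
        if (any(viol < -1e-8))
            stop("dendrogram heights decrease beyond numerical noise")
        dend$height <- cummax(dend$height)
    }
    branch <- stats::cutree(dend, h = cutHeight)
    sizes <- table(branch)
    big <- as.integer(names(sizes)[sizes >= minModuleSize])
    firstMember <- vapply(big, function(b) min(which(branch == b)),
                          integer(1))
    ord <- big[order(-as.integer(sizes[as.character(big)]), firstMember)]
    labels <- rep("grey", length(branch))
    names(labels) <- names(branch)
    for (i in seq_along(ord))
        labels[branch == ord[i]] <- moduleColorAlias(i)
    list(labels = labels, moduleOrder = moduleColorAlias(seq_along(ord)),
         cutHeight = cutHeight)
}

#' Module eigengene
#'
#' First right singular vector of the module's feature-standardised
#' expression over samples: rows are z-scored, the eigengene is the first
#' right singular vector (unit Euclidean norm), its sign is oriented so
#' that it correlates positively with the per-sample mean of the
#' standardised rows, and \code{varianceExplained} is the first squared
#' singular value over the total.
#'
#' @param x numeric matrix, module features x samples (>= 2 features).
#' @return list: \code{eigengene} (length = samples, unit norm),
#'   \code{varianceExplained}, \code{sign}.
#' @export
moduleEigengene <- function(x) {
    x <- as.matrix(x)
    if (nrow(x) < 2) stop("a module needs >= 2 features")
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0))
        stop("constant feature row(s): ",
             paste(utils::head(rownames(x)[sds == 0], 5), collapse = ", "))
    z <- t(scale(t(x)))
    sv <- svd(z)
    e <- sv$v[, 1]
    s <- 1
    if (stats::cor(e, colMeans(z)) < 0) { e <- -e; s <- -1 }
    list(eigengene = stats::setNames(e, colnames(x)),
         varianceExplained = sv$d[1]^2 / sum(sv$d^2), sign = s)
}

#' Module-stage correlation statistics
#'
#' Pearson correlation between an eigengene and each one-hot stage
#' indicator over all samples (n = 21 at the default design), with the
#' Student-t p-value at n - 2 degrees of freedom:
#' \code{t = r sqrt(n - 2) / sqrt(1 - r^2)}, two-sided.  A module-stage
#' pair is significant when \code{r > moduleTraitRMin} and
#' \code{p < moduleTraitAlpha}.
#'
#' @param eigengene per-sample eigengene values.
#' @param stage per-sample stage factor.
#' @param config a \linkS4class{PipelineConfig}.
#' @return data.frame: stage, r, t, df, p_value, significant.
#' @export
moduleTraitCorrelation <- function(eigengene, stage,
                                   config = pipelineConfig()) {
    stage <- droplevels(as.factor(stage))
    n <- length(eigengene)
    stopifnot(length(stage) == n)
    out <- lapply(levels(stage), function(s) {
        ind <- as.numeric(stage == s)
        r <- stats::cor(eigengene, ind)
        df <- n - 2
        if (abs(r) >= 1 - 1e-15) {
            t <- sign(r) * Inf; p <- 0
        } else {
            t <- r * sqrt(df) / sqrt(1 - r^2)
            p <- 2 * stats::pt(-abs(t), df)
        }
        data.frame(stage = s, r = r, t = t, df = df, p_value = p,
                   significant = r > config@moduleTraitRMin &
                       p < config@moduleTraitAlpha)
    })
    do.call(rbind, c(out, make.row.names = FALSE))
}

#' Temporal classification of modules
#'
#' Let S be the stages with a significant positive module-stage
#' correlation.  A module is \code{early} when |S| >= 2 and S lies within
#' the first three stages, \code{late} when |S| >= 2 and S lies within the
#' last three, \code{stage_specific} when |S| = 1, \code{none} when S is
#' empty, and \code{mixed} otherwise.
#'
#' @param stats module-stage statistics
#'   (\code{\link{moduleTraitCorrelation}} output).
#' @param stageOrder ordered stage labels.
#' @return a single class string.
#' @export
classifyTemporalModule <- function(stats, stageOrder = DEFAULT_STAGES) {
    S <- stats$stage[stats$significant]
    ns <- length(stageOrder)
    early <- stageOrder[seq_len(min(3, ns))]
    late <- stageOrder[seq.int(max(1, ns - 2), ns)]
    if (length(S) == 0) return("none")
    if (length(S) == 1) return("stage_specific")
    if (all(S %in% early)) return("early")
    if (all(S %in% late)) return("late")
    "mixed"
}

#' Detect co-expression modules
#'
#' End-to-end module detection on a feature set: correlation, soft
#' threshold (unless \code{beta} is given), signed adjacency, TOM,
#' average-linkage tree, static branch cut, eigengenes, module-stage
#' statistics and temporal classification.
#'
#' @param se a \linkS4class{StageExpression}.
#' @param features features to network (e.g. the DE lncRNA union).
#' @param config a \linkS4class{PipelineConfig}.
#' @param beta optional fixed soft-threshold power.  When NULL, the
#'   scale-free criterion picks it; if the criterion never reaches its fit
#'   target (modular expression need not have a scale-free degree
#'   distribution, and an argmax over a flat fit profile is unstable) the
#'   standard signed-network power \code{fallbackBeta} is used instead.
#' @param fallbackBeta power used when the scale-free fit target is not
#'   reached (default 12).
#' @param minModuleSize,cutHeight see \code{\link{treeCutModules}}.
#' @return a \linkS4class{ModuleSet}.
#' @export
detectModules <- function(se, features = NULL, config = pipelineConfig(),
                          beta = NULL, fallbackBeta = 12,
                          minModuleSize = 20, cutHeight = NULL) {
    if (!is.null(features)) se <- se[features, ]
    r <- pearsonMatrix(se)
    if (is.null(beta)) {
        st <- pickSoftThreshold(r)
        beta <- if (st$reachedTarget) st$beta else fallbackBeta
    }
    adj <- signedAdjacency(r, beta)
    tom <- tomSimilarity(adj)
    dend <- averageLinkage(1 - tom)
    cut <- treeCutModules(dend, minModuleSize = minModuleSize,
                          cutHeight = cutHeight)
    x <- log2Fpkm(se)
    st <- stageOf(se)
    eig <- matrix(numeric(), 0, ncol(x))
    ve <- numeric(); tcl <- character(); stats <- list()
    for (m in cut$moduleOrder) {
        memb <- names(cut$labels)[cut$labels == m]
        me <- moduleEigengene(x[memb, , drop = FALSE])
        eig <- rbind(eig, me$eigengene)
        ve[m] <- me$varianceExplained
        ts <- moduleTraitCorrelation(me$eigengene, st, config)
        ts$module <- m
        stats[[m]] <- ts
        tcl[m] <- classifyTemporalModule(ts, levels(st))
    }
    rownames(eig) <- cut$moduleOrder
    colnames(eig) <- colnames(x)
    new("ModuleSet", labels = cut$labels, moduleOrder = cut$moduleOrder,
        eigengenes = eig, varianceExplained = ve,
        traitStats = if (length(stats))
            do.call(rbind, c(stats, make.row.names = FALSE)) else
            data.frame(),
        temporalClass = tcl, dendrogram = dend, beta = as.numeric(beta),
        cutHeight = cut$cutHeight)
}
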