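stages21 <- rep(c("F45", "F65", "F90", "F120", "F135", "B1", "B90"),
                each = 3)

test_that("Pearson matrix matches a covariance-ratio oracle", {
    set.seed(51)
    m <- matrix(rexp(10 * 21), 10, 21, dimnames = list(paste0("f", 1:10),
                                                       NULL))
    se <- StageExpression(m, stages21)
    r <- pearsonMatrix(se)
    expect_equal(diag(r), rep(1, 10), ignore_attr = TRUE)
    expect_true(isSymmetric(unname(r)))
    x <- log2(m + 1)
    for (i in 1:5) for (j in 6:10) {
        xi <- x[i, ]; xj <- x[j, ]
        oracle <- sum((xi - mean(xi)) * (xj - mean(xj))) /
            sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
        expect_equal(r[i, j], oracle, tolerance = 1e-12)
    }
    ## anti-correlated features
    m2 <- rbind(a = 2^(1:21), b = 2^(21:1)) - 1
    se2 <- StageExpression(m2, stages21)
    expect_equal(pearsonMatrix(se2)["a", "b"], -1)
    ## zero-variance features are an error naming the offender
    m3 <- m; m3[3, ] <- 7
    expect_error(pearsonMatrix(StageExpression(m3, stages21)), "f3")
})

test_that("signed adjacency follows the closed form", {
    expect_equal(signedAdjacency(matrix(1, 2, 2), 6)[1, 2], 1)
    expect_equal(signedAdjacency(matrix(c(1, -1, -1, 1), 2), 6)[1, 2], 0)
    expect_equal(signedAdjacency(matrix(c(1, 0, 0, 1), 2), 2)[1, 2], 0.25)
    expect_error(signedAdjacency(diag(2), 0.5))
})

test_that("TOM equals the brute-force formula and stays in [0, 1]", {
    ## closed form at n = 2: TOM_12 = a_12
    a2 <- matrix(c(1, 0.4, 0.4, 1), 2)
    expect_equal(tomSimilarity(a2)[1, 2], 0.4)
    ## disconnected graph
    expect_equal(tomSimilarity(diag(5))[1, 2], 0)
    set.seed(52)
    for (rep in 1:200) {
        n <- sample(3:12, 1)
        a <- matrix(runif(n * n), n)
        a <- (a + t(a)) / 2
        diag(a) <- 1
        tom <- tomSimilarity(a)
        expect_equal(unname(tom), tomOracle(a), tolerance = 1e-12)
        expect_true(all(tom >= 0 - 1e-12 & tom <= 1 + 1e-12))
        expect_true(isSymmetric(unname(tom)))
    }
    expect_error(tomSimilarity(matrix(runif(9), 3)), "symmetric")
})

test_that("average linkage reproduces UPGMA heights", {
    ## identical features merge at height zero
    d0 <- matrix(0, 2, 2)
    h0 <- averageLinkage(d0)
    expect_equal(h0$height, 0)
    ## hand-computed three-point case
    d3 <- matrix(0, 3, 3)
    d3[1, 2] <- d3[2, 1] <- 0.1
    d3[1, 3] <- d3[3, 1] <- 0.8
    d3[2, 3] <- d3[3, 2] <- 0.9
    h3 <- averageLinkage(d3)
    expect_equal(h3$height, c(0.1, 0.85))
    ## 15-feature random dissimilarity against the naive re-derivation
    set.seed(53)
    for (rep in 1:5) {
        m <- matrix(runif(15 * 15), 15)
        d <- (m + t(m)) / 2
        diag(d) <- 0
        expect_equal(averageLinkage(d)$height, upgmaHeightsOracle(d),
                     tolerance = 1e-12)
    }
    expect_error(averageLinkage(matrix(runif(16), 4)), "symmetric")
    dd <- matrix(0.5, 3, 3)
    expect_error(averageLinkage(dd), "diagonal")
})

test_that("static tree cut separates planted blocks and labels by size", {
    ## two blocks of 30 with near-zero cross adjacency
    n <- 60
    a <- matrix(0.01, n, n)
    a[1:30, 1:30] <- 0.9
    a[31:60, 31:60] <- 0.85
    diag(a) <- 1
    rownames(a) <- colnames(a) <- paste0("f", 1:n)
    tom <- tomSimilarity(a)
    cut <- treeCutModules(averageLinkage(1 - tom), minModuleSize = 20)
    expect_equal(sort(unique(cut$labels)), sort(c("turquoise", "blue")))
    expect_equal(sum(cut$labels == "grey"), 0)
    ## larger block gets the first colour
    sizes <- table(cut$labels)
    expect_true(all(diff(as.integer(sizes[cut$moduleOrder])) <= 0))
    ## all-dissimilar features with min size 20 are all grey
    d <- 1 - diag(15)
    rownames(d) <- colnames(d) <- paste0("g", 1:15)
    cut2 <- treeCutModules(averageLinkage(d), minModuleSize = 20)
    expect_true(all(cut2$labels == "grey"))
    expect_error(treeCutModules(averageLinkage(d), minModuleSize = 1),
                 ">= 2")
})

test_that("module eigengene agrees with power iteration up to sign", {
    ## identical rows: the standardized profile carries all variance
    x <- matrix(rep(sin(1:21), each = 4) * 3 + 5, 4, 21, byrow = FALSE)
    me <- moduleEigengene(x)
    expect_equal(me$varianceExplained, 1)
    z <- t(scale(t(x)))
    expect_gt(cor(me$eigengene, colMeans(z)), 0.999)
    set.seed(54)
    for (rep in 1:50) {
        m <- matrix(rnorm(10 * 21), 10, 21)
        me <- moduleEigengene(m)
        v <- eigengeneOracle(t(scale(t(m))))
        agree <- min(sum((me$eigengene - v)^2), sum((me$eigengene + v)^2))
        expect_lt(sqrt(agree), 1e-8)
        expect_equal(sum(me$eigengene^2), 1, tolerance = 1e-12)
        expect_gte(cor(me$eigengene, colMeans(t(scale(t(m))))), 0)
        expect_gt(me$varianceExplained, 0)
        expect_lte(me$varianceExplained, 1)
    }
    ## eigengene is invariant to feature ordering
    set.seed(55)
    m <- matrix(rnorm(8 * 21), 8, 21)
    e1 <- moduleEigengene(m)$eigengene
    e2 <- moduleEigengene(m[sample(8), ])$eigengene
    expect_equal(e1, e2, tolerance = 1e-8)
    expect_error(moduleEigengene(matrix(1, 2, 21)), "constant")
    expect_error(moduleEigengene(matrix(rnorm(21), 1, 21)), ">= 2")
})

test_that("module-stage statistics follow the Student-t closed form", {
    set.seed(56)
    e <- rnorm(21)
    st <- factor(stages21, levels = unique(stages21))
    ms <- moduleTraitCorrelation(e, st)
    expect_equal(nrow(ms), 7)
    for (i in seq_len(7)) {
        ct <- cor.test(e, as.numeric(st == levels(st)[i]))
        expect_equal(ms$r[i], unname(ct$estimate), tolerance = 1e-12)
        expect_equal(ms$p_value[i], ct$p.value, tolerance = 1e-12)
        expect_equal(ms$df[i], 19)
    }
    ## perfect correlation gives p = 0 exactly
    ePerf <- as.numeric(st == "F45")
    rp <- moduleTraitCorrelation(ePerf, st)
    expect_equal(rp$p_value[rp$stage == "F45"], 0)
    expect_true(rp$significant[rp$stage == "F45"])
    ## p decreases strictly with |r| at fixed n
    rs <- seq(0.05, 0.95, by = 0.05)
    ps <- sapply(rs, function(r) {
        t <- r * sqrt(19) / sqrt(1 - r^2)
        2 * pt(-abs(t), 19)
    })
    expect_true(all(diff(ps) < 0))
})

test_that("temporal classification partitions the significance patterns", {
    mk <- function(sig) data.frame(
        stage = c("F45", "F65", "F90", "F120", "F135", "B1", "B90"),
        significant = sig)
    sig <- rep(FALSE, 7)
    expect_equal(classifyTemporalModule(mk(sig)), "none")
    sig1 <- sig; sig1[3] <- TRUE
    expect_equal(classifyTemporalModule(mk(sig1)), "stage_specific")
    sigE <- sig; sigE[1:3] <- TRUE
    expect_equal(classifyTemporalModule(mk(sigE)), "early")
    sigE2 <- sig; sigE2[1:2] <- TRUE
    expect_equal(classifyTemporalModule(mk(sigE2)), "early")
    sigL <- sig; sigL[5:7] <- TRUE
    expect_equal(classifyTemporalModule(mk(sigL)), "late")
    sigM <- sig; sigM[c(1, 5)] <- TRUE
    expect_equal(classifyTemporalModule(mk(sigM)), "mixed")
})

test_that("soft-threshold selection returns a full fit table", {
    b <- simulateBundle(smallDesign(seed = 57))
    x <- b$truth$lncIds[1:80]
    r <- pearsonMatrix(b$expression, x)
    st <- pickSoftThreshold(r, powers = 1:10)
    expect_equal(nrow(st$fitTable), 10)
    expect_true(st$beta %in% 1:12)
    ## pure-noise data: low fit or fallback, never an error
    set.seed(58)
    noise <- matrix(rexp(100 * 21), 100, 21,
                    dimnames = list(paste0("n", 1:100), NULL))
    rn <- pearsonMatrix(StageExpression(noise, stages21))
    stn <- pickSoftThreshold(rn, powers = 1:10)
    expect_true(is.finite(stn$beta))
    ## degenerate all-equal connectivity exercises the fallback
    ones <- matrix(1, 25, 25)
    expect_warning(stf <- pickSoftThreshold(ones, powers = 1:5),
                   "degenerate|fall")
    expect_equal(stf$beta, 12)
})

test_that("end-to-end module detection recovers planted structure", {
    b <- simulateBundle(smallDesign(seed = 59))
    lnc <- b$truth$lncIds
    planted <- names(b$truth$moduleOf)[b$truth$moduleOf != "background"]
    planted <- intersect(planted, lnc)
    ms <- detectModules(b$expression, features = lnc)
    expect_equal(plantedModuleARI(ms, b$truth$moduleOf), 1.0,
                 tolerance = 0.05)
    mp <- matchPlantedModules(ms, b$design, b$truth$moduleOf)
    expect_true(all(mp$classCorrect))
    ## labels are total: every clustered feature gets exactly one label
    expect_setequal(names(moduleLabels(ms)), lnc)
    sizes <- table(moduleLabels(ms))[ms@moduleOrder]
    expect_true(all(diff(as.integer(sizes)) <= 0))
    expect_true(all(ms@varianceExplained > 0 &
                    ms@varianceExplained <= 1))
})
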