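stages21n <- rep(c("F45", "F65", "F90", "F120", "F135", "B1", "B90"),
                 each = 3)


test_that("cis window is inclusive at exactly 100 kb", {
    annot <- cisToy(c(0, 100000, 100001, 5000))
    ## gap 0 means abutting: distance 0
    e <- cisTargets(annot, "lnc1")
    expect_setequal(e$gene, c("g1", "g2", "g4"))
    expect_equal(e$distance_bp[e$gene == "g2"], 100000)
    expect_false("g3" %in% e$gene)
    ## overlapping gene has distance 0
    ov <- toyAnnotation(rbind(
        data.frame(chrom = "chr1", start = c(1000, 1500), end = c(1200, 1700),
                   strand = "+", transcript_id = "lnc1", gene_id = "gl1",
                   biotype = "lncRNA_candidate"),
        data.frame(chrom = "chr1", start = 1100, end = 2500, strand = "-",
                   transcript_id = "m1", gene_id = "g1", biotype = "mRNA")))
    eo <- cisTargets(ov, "lnc1")
    expect_equal(eo$distance_bp, 0)
    ## different chromosome is never a cis target
    far <- toyAnnotation(rbind(
        data.frame(chrom = "chr1", start = c(1000, 1500), end = c(1200, 1700),
                   strand = "+", transcript_id = "lnc1", gene_id = "gl1",
                   biotype = "lncRNA_candidate"),
        data.frame(chrom = "chr2", start = 1100, end = 2500, strand = "+",
                   transcript_id = "m1", gene_id = "g1", biotype = "mRNA")))
    expect_equal(nrow(cisTargets(far, "lnc1")), 0)
})

test_that("cis targets equal an exhaustive interval-scan oracle", {
    set.seed(61)
    gaps <- sort(sample(0:250000, 50))
    annot <- cisToy(gaps)
    e <- cisTargets(annot, "lnc1")
    oracle <- paste0("g", which(gaps <= 100000))
    expect_setequal(e$gene, oracle)
    ## symmetry: the inclusive gap metric reads the same from either side
    expect_true(all(e$distance_bp <= 100000))
    expect_equal(sort(e$distance_bp),
                 sort(gaps[gaps <= 100000]))
})

test_that("co-expression targeting is strict at the correlation cut", {
    base <- 2^(sin(1:21) * 2 + 5)
    m <- rbind(lnc1 = base, g1 = base, g2 = rexp(21) + 1)
    se <- StageExpression(m, stages21n)
    e <- coexpressionTargets(se, "lnc1", c("g1", "g2"))
    expect_true("g1" %in% e$gene)          # identical profiles: r = 1
    expect_equal(e$r[e$gene == "g1"], 1)
    ## a pair sitting exactly at the cut is excluded (strict >)
    set.seed(62)
    x <- rnorm(21); y <- rnorm(21)
    rxy <- cor(log2(2^x + 1 - 1 + 1), log2(2^y + 1 - 1 + 1))
    m2 <- rbind(lnc1 = 2^x - min(2^x), gA = 2^y - min(2^y))
    m2 <- pmax(m2, 0)
    se2 <- StageExpression(m2, stages21n)
    robs <- cor(log2(m2[1, ] + 1), log2(m2[2, ] + 1))
    e2 <- coexpressionTargets(se2, "lnc1", "gA",
                              pipelineConfig(coexprAbsRMin = abs(robs)))
    expect_equal(nrow(e2), 0)
    ## zero-variance rows are skipped with a warning
    m3 <- rbind(lnc1 = base, flat = rep(3, 21))
    se3 <- StageExpression(m3, stages21n)
    expect_warning(e3 <- coexpressionTargets(se3, "lnc1", "flat"),
                   "zero-variance")
    expect_equal(nrow(e3), 0)
})

test_that("planted same-module lnc-mRNA pairs are recovered", {
    ## pre-build Monte-Carlo put pair sensitivity near 0.77 for two-stage
    ## modules and 0.30 for the single-stage module at default noise;
    ## floors below are the frozen empirical values minus margin
    b <- simulateBundle(smallDesign(seed = 63))
    x <- b$expression
    sens <- function(lab) {
        lncs <- intersect(b$truth$lncIds,
                          names(b$truth$moduleOf)[b$truth$moduleOf == lab])
        mrnas <- intersect(b$truth$mrnaIds,
                           names(b$truth$moduleOf)[b$truth$moduleOf == lab])
        e <- coexpressionTargets(x, lncs, mrnas)
        nrow(e) / (length(lncs) * length(mrnas))
    }
    expect_gt(sens("earlyA"), 0.6)
    expect_gt(sens("lateA"), 0.6)
    expect_gt(sens("peakF90"), 0.15)
})

test_that("network assembly applies the fold-change screen", {
    de <- list(
        p1 = data.frame(feature_id = c("l1", "l2", "l3"),
                        stage_a = "F45", stage_b = "F90",
                        log2_fc = c(3, 0.5, 2), t = 1, df = 4,
                        p_value = c(0.001, 0.001, 0.5),
                        direction = "up", de = c(TRUE, TRUE, FALSE)))
    cis <- data.frame(lncrna = c("l1", "l2", "l3"),
                      gene = c("g1", "g2", "g3"), mode = "cis",
                      distance_bp = c(0L, 10L, 20L))
    coex <- data.frame(lncrna = "l1", gene = c("g1", "g4"),
                       mode = "coexpression", r = c(0.99, -0.97))
    net <- buildTargetNetwork(de, cis, coex)
    ## l2 fails |log2FC| >= 1; l3 fails p < 0.05
    expect_setequal(net@lncNodes, "l1")
    ## duplicate (l1, g1) collapses keeping both evidence records
    e11 <- networkEdges(net)[networkEdges(net)$gene == "g1", ]
    expect_equal(e11$mode, "cis+coexpression")
    expect_equal(e11$distance_bp, 0L)
    expect_equal(e11$r, 0.99)
    expect_equal(unname(networkDegree(net)["l1"]), 2L)
    expect_true(validObject(net))
    ## empty edge set gives an empty network
    net0 <- buildTargetNetwork(de, cis[0, ], coex[0, ])
    expect_equal(nrow(networkEdges(net0)), 0)
})

test_that("toy networks match rule-by-rule oracle evaluation", {
    set.seed(64)
    lncs <- paste0("l", 1:5)
    genes <- paste0("g", 1:20)
    de <- list(pp = data.frame(
        feature_id = lncs, stage_a = "F45", stage_b = "F90",
        log2_fc = runif(5, -4, 4), t = 1, df = 4,
        p_value = runif(5, 0, 0.2), direction = "up", de = NA))
    cis <- data.frame(lncrna = sample(lncs, 15, replace = TRUE),
                      gene = sample(genes, 15), mode = "cis",
                      distance_bp = sample(0:1000, 15))
    emptyCoex <- data.frame(lncrna = character(), gene = character(),
                            mode = character(), r = numeric())
    net <- buildTargetNetwork(de, cis, emptyCoex)
    admit <- de$pp$feature_id[de$pp$p_value < 0.05 &
                              abs(de$pp$log2_fc) >= 1]
    oracleEdges <- cis[cis$lncrna %in% admit, ]
    expect_equal(nrow(networkEdges(net)), nrow(oracleEdges))
    expect_setequal(net@lncNodes, unique(oracleEdges$lncrna))
    ## degree equals an independent per-node count
    for (l in net@lncNodes)
        expect_equal(unname(networkDegree(net)[l]),
                     sum(oracleEdges$lncrna == l))
})

test_that("hub extraction is strict at the degree cut and monotone", {
    mkNet <- function(degrees) {
        edges <- do.call(rbind, lapply(names(degrees), function(l)
            data.frame(lncrna = l,
                       gene = paste0("g_", l, "_", seq_len(degrees[[l]])),
                       mode = "cis", distance_bp = 0L, r = NA_real_)))
        new("TargetNetwork", edges = edges,
            lncNodes = names(degrees),
            mrnaNodes = unique(edges$gene),
            degree = c(vapply(degrees, as.integer, integer(1)),
                       stats::setNames(rep(1L, nrow(edges)), edges$gene)))
    }
    net <- mkNet(c(a = 10, b = 11, c = 20))
    h <- hubLncrnas(net)
    expect_equal(h$hubs$lncrna, c("c", "b"))   # 10 is not a hub
    expect_equal(h$hubs$degree, c(20, 11))
    expect_equal(nrow(h$subnetworks[["c"]]), 20)
    ## monotone: raising the cut never adds hubs
    h15 <- hubLncrnas(net, pipelineConfig(hubMinDegree = 15))
    expect_true(all(h15$hubs$lncrna %in% h$hubs$lncrna))
    ## random bipartite toy against a direct tabulation oracle
    set.seed(65)
    degs <- stats::setNames(sample(1:30, 8), paste0("L", 1:8))
    net2 <- mkNet(degs)
    h2 <- hubLncrnas(net2)
    expect_setequal(h2$hubs$lncrna, names(degs)[degs > 10])
})
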