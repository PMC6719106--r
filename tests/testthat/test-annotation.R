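test_that("GTF round trip preserves exon chains and arithmetic works", {
    ex <- data.frame(chrom = "chr1", start = c(101, 301), end = c(200, 400),
                     strand = "+", transcript_id = "tx1", gene_id = "g1",
                     biotype = "mRNA")
    annot <- toyAnnotation(ex)
    st <- transcriptStats(annot)
    expect_equal(st$length, 200)
    expect_equal(st$n_exons, 2)

    path <- withr::local_tempfile(fileext = ".gtf")
    writeGtf(annot, path)
    back <- readGtf(path)
    expect_identical(
        as.data.frame(exonsBy(back)[["tx1"]])[, c("start", "end", "strand")],
        as.data.frame(exonsBy(annot)[["tx1"]])[, c("start", "end", "strand")])

    ## full synthetic bundle round trip
    b <- simulateBundle(smallDesign(seed = 5))
    p2 <- withr::local_tempfile(fileext = ".gtf")
    writeGtf(b$annotation, p2)
    b2 <- readGtf(p2)
    ids <- names(exonsBy(b$annotation))
    expect_setequal(names(exonsBy(b2)), ids)
    for (id in sample(ids, 20))
        expect_equal(
            as.data.frame(exonsBy(b2)[[id]])[, c("start", "end", "strand")],
            as.data.frame(exonsBy(b$annotation)[[id]])[, c("start", "end",
                                                           "strand")])
})

test_that("malformed GTF lines are rejected with their line number", {
    p <- withr::local_tempfile(fileext = ".gtf")
    writeLines(c(
        'chr1\tsrc\texon\t10\t50\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
        'chr1\tsrc\texon\t100\t40\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
        p)
    expect_error(readGtf(p), "line 2")
    p2 <- withr::local_tempfile(fileext = ".gtf")
    writeLines(c('chr1\tsrc\texon\t10\t50'), p2)
    expect_error(readGtf(p2), "line 1.*9 tab")
    expect_error(readGtf(file.path(tempdir(), "nope.gtf")), "no such file")
})

test_that("longest ORF matches the brute-force scan and its invariants", {
    expect_equal(longestOrfLength("ATGTAA"), 6)
    expect_equal(longestOrfLength("ATGAAA"), 0)      # stop required
    expect_equal(longestOrfLength(""), 0)
    expect_equal(longestOrfLength("ATGNNNTAA"), 0)   # N interrupts
    expect_equal(longestOrfLength("ATGAAATAAATGGGGGGGTAG"), 12)
    expect_error(longestOrfLength("ATGXAA"), "A,C,G,T,N")

    set.seed(42)
    for (i in 1:25) {
        s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                   collapse = "")
        got <- longestOrfLength(s)
        expect_equal(got, orfOracle(s), info = paste("seq", i))
        expect_lte(got, nchar(s))
        if (got > 0) expect_equal(got %% 3, 0)
    }
})

test_that("positional classification follows the precedence rules", {
    ## one + strand mRNA gene with two exons and an intron
    base <- data.frame(chrom = "chr1",
                       start = c(1000, 3000), end = c(1500, 3500),
                       strand = "+", transcript_id = "m1", gene_id = "gm1",
                       biotype = "mRNA")
    anti <- data.frame(chrom = "chr1", start = c(1200, 1800),
                       end = c(1400, 1900), strand = "-",
                       transcript_id = "lncA", gene_id = "glA",
                       biotype = "lncRNA_candidate")
    intr <- data.frame(chrom = "chr1", start = c(1700, 2200),
                       end = c(1900, 2400), strand = "+",
                       transcript_id = "lncI", gene_id = "glI",
                       biotype = "lncRNA_candidate")
    faraway <- data.frame(chrom = "chr1", start = c(9000, 9500),
                          end = c(9200, 9700), strand = "+",
                          transcript_id = "lncL", gene_id = "glL",
                          biotype = "lncRNA_candidate")
    annot <- toyAnnotation(rbind(base, anti, intr, faraway))
    cls <- classifyLncrnaPosition(annot)
    expect_equal(unname(cls["lncA"]), "antisense_lncRNA")
    expect_equal(unname(cls["lncI"]), "intronic_lncRNA")
    expect_equal(unname(cls["lncL"]), "lincRNA")
    ## no coding genes at all -> everything lincRNA
    lonely <- toyAnnotation(faraway)
    expect_equal(unname(classifyLncrnaPosition(lonely)), "lincRNA")
})

test_that("classification recovers the generator's ground-truth placement", {
    b <- simulateBundle(smallDesign(seed = 2))
    cls <- classifyLncrnaPosition(b$annotation)
    expect_identical(unname(cls[names(b$truth$lncClass)]),
                     unname(b$truth$lncClass))
    ## exact apportionment of class proportions
    comp <- typeComposition(cls)
    expect_equal(sum(comp$proportion), 1, tolerance = 1e-12)
    expect_equal(comp$count[match(c("lincRNA", "antisense_lncRNA",
                                    "intronic_lncRNA"), comp$class)],
                 c(60, 36, 24))
})

test_that("structure summary medians are consistent with the oracle", {
    b <- simulateBundle(smallDesign(seed = 3))
    ss <- structureSummary(b$annotation)
    med <- ss$medians
    lnc <- med[med$biotype == "lncRNA_candidate", ]
    mrna <- med[med$biotype == "mRNA", ]
    expect_lt(lnc$median_length, mrna$median_length)
    expect_lt(lnc$median_orf, mrna$median_orf)
    expect_lt(lnc$median_exons, mrna$median_exons)
    ## ORF medians recomputed through the brute-force oracle
    tab <- ss$perTranscript
    lncTab <- tab[tab$biotype == "lncRNA_candidate", ][1:15, ]
    seqs <- transcriptMeta(b$annotation)$sequence[
        match(lncTab$transcript_id,
              transcriptMeta(b$annotation)$transcript_id)]
    expect_equal(lncTab$orf_length,
                 vapply(seqs, orfOracle, numeric(1), USE.NAMES = FALSE))
    ## trivial median
    two <- toyAnnotation(data.frame(
        chrom = "chr1", start = c(1, 1001), end = c(300, 1500),
        strand = "+", transcript_id = c("a", "b"), gene_id = c("ga", "gb"),
        biotype = "mRNA"))
    expect_equal(structureSummary(two)$medians$median_length, 400)
})

test_that("gene-level FPKM sums transcripts and conserves mass", {
    ex <- data.frame(chrom = "chr1",
                     start = c(1, 501, 2001, 5001), end = c(100, 600, 2100, 5100),
                     strand = "+",
                     transcript_id = c("t1", "t2", "t3", "t4"),
                     gene_id = c("g1", "g1", "g2", "g3"),
                     biotype = "mRNA")
    annot <- toyAnnotation(ex)
    set.seed(9)
    m <- matrix(rexp(4 * 21), 4, 21,
                dimnames = list(c("t1", "t2", "t3", "t4"), NULL))
    m["t1", 1] <- 1.5; m["t2", 1] <- 2.5
    se <- StageExpression(m, rep(c("F45", "F65", "F90", "F120", "F135",
                                   "B1", "B90"), each = 3))
    g <- geneLevelFpkm(se, annot)
    expect_equal(unname(fpkm(g)["g1", 1]), 4.0)
    expect_equal(unname(fpkm(g)["g2", ]), unname(m["t3", ]))  # identity
    expect_equal(rownames(fpkm(g)), sort(rownames(fpkm(g))))
    expect_equal(colSums(fpkm(g)), colSums(fpkm(se)))          # mass
    ## brute-force group-sum oracle
    oracle <- t(vapply(c("g1", "g2", "g3"), function(gg) {
        tx <- ex$transcript_id[ex$gene_id == gg]
        colSums(m[tx, , drop = FALSE])
    }, numeric(21)))
    expect_equal(unname(fpkm(g)), unname(oracle))
    ## unmapped transcript errors
    rownames(m)[1] <- "mystery"
    se2 <- StageExpression(m, rep(c("F45", "F65", "F90", "F120", "F135",
                                    "B1", "B90"), each = 3))
    expect_error(geneLevelFpkm(se2, annot), "mystery")
})
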