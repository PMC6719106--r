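## Independent oracles used to cross-check the package's implementations.
## Each is a deliberately naive re-derivation (loops, enumeration, closed
## forms) sharing no code with the functions it checks.

## Topological overlap by explicit triple loop.
tomOracle <- function(adj) {
    n <- nrow(adj)
    out <- matrix(1, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        l <- 0
        for (u in seq_len(n))
            if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
        ki <- sum(adj[i, -i]); kj <- sum(adj[j, -j])
        out[i, j] <- (l + adj[i, j]) / (min(ki, kj) + 1 - adj[i, j])
    }
    out
}

## Naive UPGMA: merge the closest pair, recompute average distances by
## explicit member enumeration; returns merge heights in order.
upgmaHeightsOracle <- function(d) {
    d <- as.matrix(d)
    clusters <- as.list(seq_len(nrow(d)))
    heights <- numeric()
    while (length(clusters) > 1) {
        best <- c(Inf, NA, NA)
        for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
            if (a >= b) next
            h <- mean(d[clusters[[a]], clusters[[b]]])
            if (h < best[1]) best <- c(h, a, b)
        }
        heights <- c(heights, best[1])
        merged <- c(clusters[[best[2]]], clusters[[best[3]]])
        clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    }
    heights
}

## Dominant right singular vector by power iteration on crossprod(z).
eigengeneOracle <- function(z, iters = 2000) {
    m <- crossprod(z)           # samples x samples
    v <- rep(1, ncol(z)) / sqrt(ncol(z))
    for (i in seq_len(iters)) {
        v2 <- m %*% v
        v <- v2 / sqrt(sum(v2^2))
    }
    as.numeric(v)
}

## Two-sided Fisher p by full enumeration with choose() arithmetic.
fisherOracle <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
    c1 <- sum(tab[, 1]); n <- r1 + r2
    support <- max(0, c1 - r2):min(c1, r1)
    prob <- vapply(support, function(x)
        choose(r1, x) * choose(r2, c1 - x) / choose(n, c1), numeric(1))
    obs <- prob[match(tab[1, 1], support)]
    sum(prob[prob <= obs * (1 + 1e-7)])
}

## Upper-tail hypergeometric P(X >= k) by choose() summation.
hyperTailOracle <- function(k, K, n, N) {
    xs <- k:min(K, n)
    sum(vapply(xs, function(x)
        choose(K, x) * choose(N - K, n - x) / choose(N, n), numeric(1)))
}

## Longest forward-frame ORF by brute force over every start position.
orfOracle <- function(s) {
    s <- toupper(s); L <- nchar(s)
    best <- 0
    for (i in seq_len(max(0, L - 5))) {
        if (substr(s, i, i + 2) != "ATG") next
        j <- i
        while (j + 5 <= L + 3 - 3 && j + 2 <= L - 3 + 3) {
            cod <- substr(s, j + 3, j + 5)
            if (nchar(cod) < 3) break
            if (grepl("N", substr(s, i, j + 5))) break
            if (cod %in% c("TAA", "TAG", "TGA")) {
                best <- max(best, j + 5 - i + 1)
                break
            }
            j <- j + 3
        }
    }
    best
}

## Small hand-built annotation from an exon table.
toyAnnotation <- function(exonDf) {
    lncTempo:::makeAnnotation(exonDf)
}

## Compact simulation design for fast unit tests.
smallDesign <- function(seed = 1, ...) {
    simulationDesign(
        nMrna = 300L, nLncrna = 120L,
        plantedModules = list(
            plantedModule("earlyA", "early", c("F45", "F65"), size = 25L),
            plantedModule("lateA", "late", c("B1", "B90"), size = 25L),
            plantedModule("peakF90", "stage_specific", "F90", size = 20L)),
        seed = seed, ...)
}

## lncRNA at a fixed locus plus coding genes at controlled gaps.
cisToy <- function(gaps) {
    lnc <- data.frame(chrom = "chr1", start = c(500001, 500501),
                      end = c(500200, 500700), strand = "+",
                      transcript_id = "lnc1", gene_id = "gl1",
                      biotype = "lncRNA_candidate")
    genes <- do.call(rbind, lapply(seq_along(gaps), function(i) {
        start <- 500700 + gaps[i] + 1
        data.frame(chrom = "chr1", start = start, end = start + 999,
                   strand = "+", transcript_id = paste0("m", i),
                   gene_id = paste0("g", i), biotype = "mRNA")
    }))
    toyAnnotation(rbind(lnc, genes))
}
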