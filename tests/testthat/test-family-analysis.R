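test_that("k-mer TIR distances match set arithmetic", {
    a <- paste(rep("ACGTG", 16), collapse = "") # 80 bp
    d0 <- tirDistanceMatrix(c(x = a, y = a))
    expect_equal(unname(d0["x", "y"]), 0)
    expect_equal(diag(d0), c(x = 0, y = 0))

    polyA <- paste(rep("A", 80), collapse = "")
    polyC <- paste(rep("C", 80), collapse = "")
    d1 <- tirDistanceMatrix(c(x = polyA, y = polyC))
    expect_equal(unname(d1["x", "y"]), 1)

    set.seed(14)
    seqs <- c(a = randSeq(80), b = randSeq(80), c = randSeq(120))
    d <- tirDistanceMatrix(seqs)
    expect_true(isSymmetric(d))
    for (p in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
        expect_equal(unname(d[p[1], p[2]]),
                     oracleKmerDist(substr(seqs[[p[1]]], 1, 80),
                                    substr(seqs[[p[2]]], 1, 80), 5))
    }
    expect_warning(tirDistanceMatrix(c(s = randSeq(40))), "shorter")
})

test_that("complete-linkage cut recovers planted TIR groups", {
    set.seed(26)
    mk <- function(core, n) {
        vapply(seq_len(n), function(i) {
            ch <- strsplit(core, "")[[1]]
            at <- sample(80, 4)
            ch[at] <- sample(c("A", "C", "G", "T"), 4, replace = TRUE)
            paste(ch, collapse = "")
        }, "")
    }
    coreA <- randSeq(80); coreB <- randSeq(80)
    seqs <- c(mk(coreA, 5), mk(coreB, 5))
    names(seqs) <- paste0("e", 1:10)
    d <- tirDistanceMatrix(seqs)
    cut <- clusterTirMatrix(d, nGroups = 2)
    g <- cut$groups[names(seqs)]
    expect_length(unique(g[1:5]), 1)
    expect_length(unique(g[6:10]), 1)
    expect_true(g[1] != g[10])

    everyOwn <- clusterTirMatrix(d, nGroups = 10)
    expect_equal(length(unique(everyOwn$groups)), 10)
    expect_error(clusterTirMatrix(d, nGroups = 11), "exceeds")

    # input order never changes the grouping
    perm <- sample(10)
    cut2 <- clusterTirMatrix(d[perm, perm], nGroups = 2)
    expect_equal(outer(cut2$groups[names(seqs)], cut2$groups[names(seqs)], "=="),
                 outer(g, g, "=="))
})

test_that("local pair discovery respects the window and pair arithmetic", {
    mk <- function(starts, cluster, strand = "+") {
        gr <- GenomicRanges::GRanges("c1",
            IRanges::IRanges(starts, width = 500), strand = strand)
        S4Vectors::mcols(gr)$element_id <- paste0("e", seq_along(starts))
        S4Vectors::mcols(gr)$cluster_id <- cluster
        S4Vectors::mcols(gr)$superfamily <- "X"
        gr
    }
    two <- mk(c(1000, 51500), c(1, 1))
    p <- findLocalPairs(two)
    expect_equal(nrow(p), 1)
    expect_true(p$same_cluster)
    expect_equal(p$distance, 50000L)

    far <- mk(c(1000, 151600), c(1, 1))
    expect_equal(nrow(findLocalPairs(far)), 0)

    four <- mk(c(1000, 21000, 41000, 61000), c(1, 1, 2, 2))
    p4 <- findLocalPairs(four)
    expect_equal(nrow(p4), choose(4, 2))
    expect_equal(sum(p4$same_cluster), 2)

    # overlapping elements have distance zero
    ovl <- mk(c(1000, 1200), c(1, 2))
    expect_equal(findLocalPairs(ovl)$distance, 0L)
})

test_that("one-sided chi-squared matches the closed-form oracle", {
    set.seed(37)
    for (i in 1:100) {
        n1 <- sample(5:200, 1); n2 <- sample(5:2000, 1)
        k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
        got <- packScan:::.oneSidedChi2(k1, n1, k2, n2)
        if (!is.na(got$flag) && got$flag == "degenerate") {
            tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
            expect_true(any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        } else {
            expect_equal(got$p, oracleOneSidedChi2(k1, n1, k2, n2),
                         tolerance = 1e-12)
        }
    }
})

test_that("local hopping is detected for clustered, not uniform, insertions", {
    # 10 members mutually local on one contig, 1000 distant non-members
    mem <- GenomicRanges::GRanges("c1",
        IRanges::IRanges(seq(1e4, by = 2e4, length.out = 10), width = 500))
    non <- GenomicRanges::GRanges(rep(paste0("d", 1:1000)),
        IRanges::IRanges(1e4, width = 500))
    gr <- suppressWarnings(c(mem, non)) # deliberately disjoint contigs
    S4Vectors::mcols(gr)$element_id <- paste0("e", seq_along(gr))
    S4Vectors::mcols(gr)$cluster_id <- rep(c(1L, 2L), c(10, 1000))
    S4Vectors::mcols(gr)$superfamily <- "X"
    res <- localHoppingTest(gr, clusterId = 1)
    expect_lt(res$p, 1e-4)
    expect_equal(res$p, oracleOneSidedChi2(10, 10, 0, 1000))

    # equal proportions carry no evidence of enrichment
    flat <- packScan:::.oneSidedChi2(5, 10, 500, 1000)
    expect_gte(flat$p, 0.5)

    # pooling across clusters of a superfamily
    S4Vectors::mcols(gr)$cluster_id <- rep(c(1L, 1L, 2L), c(5, 5, 1000))
    pooled <- localHoppingTest(gr, superfamily = "X")
    expect_true(is.numeric(pooled$p))
    expect_equal(sum(pooled$counts[c("n1", "n2")] > 0), 2)
})

test_that("orientation concordance reproduces printed examples", {
    p <- data.frame(same_cluster = rep(TRUE, 15),
                    same_orientation = rep(c(TRUE, FALSE), c(12, 3)))
    expect_equal(orientationConcordance(p), 0.80)
    p13 <- data.frame(same_cluster = rep(TRUE, 13),
                      same_orientation = rep(c(TRUE, FALSE), c(12, 1)))
    expect_equal(round(100 * orientationConcordance(p13)), 92)
    allSame <- data.frame(same_cluster = TRUE, same_orientation = TRUE)
    expect_equal(orientationConcordance(allSame), 1.0)
    expect_message(
        expect_true(is.na(orientationConcordance(
            data.frame(same_cluster = FALSE, same_orientation = TRUE)))),
        "undefined")
})

test_that("TSD composition fractions and tables are exact", {
    mk <- function(tsds) {
        gr <- GenomicRanges::GRanges("c1",
            IRanges::IRanges(seq_along(tsds) * 1000, width = 400))
        S4Vectors::mcols(gr)$tsd_5 <- tsds
        gr
    }
    expect_equal(tsdComposition(mk(rep("TA", 8)), "TA")$fraction, 1.0)
    expect_equal(tsdComposition(mk(rep(c("TA", "TC"), 4)), "TA")$fraction, 0.5)
    mix <- mk(rep(c("TTA", "TAA", "GGC"), c(6, 3, 1)))
    comp <- tsdComposition(mix, "TTA")
    expect_equal(comp$fraction, 0.6)
    expect_equal(as.integer(comp$table[c("TTA", "TAA", "GGC")]),
                 c(6L, 3L, 1L))
})

test_that("simulated local hopping produces enrichment and concordance", {
    fams <- list(
        familySpec("HopA", "GATTCGCAGGCCTAA", tsdLength = 6, nMembers = 8,
                   internalLength = 450, hopFraction = 0.5, revFraction = 0.25),
        familySpec("HopB", "CCATGGTGCGTTACC", tsdLength = 6, nMembers = 8,
                   internalLength = 600, hopFraction = 0.5, revFraction = 0.25))
    sim <- simulateGenome(simulationConfig(57, genomeLength = 3e6,
        families = fams, nOutwardDecoys = 0, nSingletons = 0, nNRich = 0))
    res <- packSearch(simGenome(sim), simQueries(sim), genomePrefix = "Hop")
    expect_length(res, 16)
    pairs <- findLocalPairs(teRanges(res))
    expect_gt(sum(pairs$same_cluster), 0)
    conc <- orientationConcordance(pairs)
    expect_gte(conc, 0.5) # hop mates are planted in matching orientation
    hop <- localHoppingTest(teRanges(res), superfamily = "HopA")
    expect_lt(hop$p, 0.05)
})
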