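test_that("exact and near-exact seed matches are located precisely", {
    g <- Biostrings::DNAStringSet(c(c1 = "TTCACTACAATT"))
    hits <- findTirMatches(g, "CACTACAA", 0)
    expect_length(hits, 1)
    expect_equal(IRanges::start(hits), 3L)
    expect_equal(IRanges::end(hits), 10L)
    expect_equal(S4Vectors::mcols(hits)$edit_distance, 0L)

    g2 <- Biostrings::DNAStringSet(c(c1 = "TTCACTGCAATT"))
    hits2 <- findTirMatches(g2, "CACTACAA", 1)
    expect_length(hits2, 1)
    expect_equal(S4Vectors::mcols(hits2)$edit_distance, 1L)

    expect_error(findTirMatches(g, "ACGTA", 0), "at least 6")
    expect_error(findTirMatches(g, "CACTACAA", 8), "smaller than the seed")
})

test_that("N mismatches everything in TIR matching", {
    g <- Biostrings::DNAStringSet(c(c1 = "TTTAAANAAATTT"))
    expect_length(findTirMatches(g, "AAAAAAA", 0), 0)
    h <- findTirMatches(g, "AAAAAAA", 1)
    expect_true(length(h) >= 1)
    expect_true(all(S4Vectors::mcols(h)$edit_distance == 1L))
    # an N in the seed matches nothing either, not even genomic N
    expect_length(findTirMatches(g, "AAANAAA", 0), 0)
    expect_equal(levDist("NN", "NN"), 2L)
    expect_equal(levDist("TA", "TC"), 1L)
})

test_that("matcher equals the exhaustive window oracle on random sequences", {
    set.seed(91)
    for (rep in 1:12) {
        text <- randSeq(1500)
        m <- sample(8:15, 1)
        budget <- sample(0:3, 1)
        seed <- if (rep %% 3 == 0) {
            # implant the seed so hits are guaranteed
            at <- sample(500, 1)
            s <- substr(text, at, at + m - 1L)
            s
        } else randSeq(m)
        g <- Biostrings::DNAStringSet(c(c1 = text))
        got <- findTirMatches(g, seed, budget)
        want <- oracleTirMatches(text, seed, budget)
        expect_equal(length(got), nrow(want))
        if (nrow(want)) {
            expect_equal(IRanges::start(got), want$start)
            expect_equal(IRanges::end(got), want$end)
            expect_equal(S4Vectors::mcols(got)$edit_distance, want$dist)
        }
    }
})

test_that("levDist agrees with the adist oracle including the N rule", {
    set.seed(13)
    a <- replicate(60, randSeq(sample(2:12, 1), c("A", "C", "G", "T", "N")))
    b <- replicate(60, randSeq(sample(2:12, 1), c("A", "C", "G", "T", "N")))
    expect_equal(levDist(a, b), oracleLev(a, b))
})

test_that("pairing honours orientation, width window and multiplicity", {
    q <- TirQuery("X", "CACTACAA", tsdLength = 3, widthMin = 300,
                  widthMax = 15000)
    fwd <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 50, 900),
                                                         width = 8),
                                  edit_distance = 0L)
    rev <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(493, 700),
                                                         width = 8),
                                  edit_distance = 0L)
    # width from position 1: 500 and 707; from 50: 451 and 658; from 900: none
    out <- pairCandidates(fwd, rev, q)
    expect_length(out, 4)
    expect_true(all(IRanges::width(out) >= 300 & IRanges::width(out) <= 15000))

    # too-short pairing rejected: reverse hit ending at 200 gives width 200
    rev2 <- GenomicRanges::GRanges("c1", IRanges::IRanges(193, width = 8),
                                   edit_distance = 0L)
    expect_length(pairCandidates(fwd, rev2, q), 0)

    # 3 forward x 2 reverse all mutually compatible
    fwd3 <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 10, 20),
                                                          width = 8),
                                   edit_distance = 0L)
    rev3 <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(800, 1000),
                                                          width = 8),
                                   edit_distance = 0L)
    expect_length(pairCandidates(fwd3, rev3, q), 6)
})

test_that("TSD verification keeps identical flanks and rejects edge cases", {
    tsd <- "ACGTACGT"
    inner <- randSeq(400)
    text <- paste0(randSeq(50), tsd, inner, tsd, randSeq(50))
    g <- Biostrings::DNAStringSet(c(c1 = text))
    cand <- GenomicRanges::GRanges("c1", IRanges::IRanges(59, 58 + 400))
    q <- TirQuery("X", "CACTACAA", tsdLength = 8, tsdMismatch = 0)
    kept <- checkTsd(g, cand, q)
    expect_length(kept, 1)
    expect_equal(S4Vectors::mcols(kept)$tsd_5, tsd)
    expect_equal(S4Vectors::mcols(kept)$tsd_dist, 0L)

    # differing flanks beyond budget are rejected
    text2 <- paste0(randSeq(50), "TA", inner, "TC", randSeq(50))
    g2 <- Biostrings::DNAStringSet(c(c1 = text2))
    cand2 <- GenomicRanges::GRanges("c1", IRanges::IRanges(53, 52 + 400))
    q2 <- TirQuery("X", "CACTACAA", tsdLength = 2, tsdMismatch = 0)
    expect_length(checkTsd(g2, cand2, q2), 0)

    # flush with the contig edge: no flank, mandatory rejection
    gEdge <- Biostrings::DNAStringSet(c(c1 = paste0(inner, tsd)))
    candEdge <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 400))
    expect_message(res <- checkTsd(gEdge, candEdge, q), "contig edge")
    expect_length(res, 0)
})

test_that("deduplication keeps the widest candidate per overlapping set", {
    gr <- function(s, e) GenomicRanges::GRanges("c1", IRanges::IRanges(s, e))
    both <- c(gr(100, 900), gr(300, 700))
    out <- dedupCandidates(both)
    expect_length(out, 1)
    expect_equal(IRanges::start(out), 100L)
    expect_equal(IRanges::end(out), 900L)

    ident <- c(gr(100, 900), gr(100, 900))
    expect_length(dedupCandidates(ident), 1)

    disjoint <- c(gr(100, 500), gr(700, 1200))
    expect_length(dedupCandidates(disjoint), 2)

    # tie on width: leftmost start wins
    tied <- c(gr(200, 699), gr(150, 649))
    out2 <- dedupCandidates(tied)
    expect_equal(IRanges::start(out2), 150L)
})

test_that("scanning is strand-symmetric", {
    set.seed(5)
    tsd <- "GATTACA"
    seed <- "CAGGGATGAAA"
    body <- paste0(seed, randSeq(600), revComp(seed))
    text <- paste0(randSeq(300), tsd, body, tsd, randSeq(300))
    g <- Biostrings::DNAStringSet(c(c1 = text))
    q <- TirQuery("hAT", seed, tsdLength = 7)
    fwdScan <- scanGenome(g, q)
    rcg <- Biostrings::reverseComplement(g)
    names(rcg) <- names(g)
    rcScan <- scanGenome(rcg, q)
    expect_length(fwdScan, 1)
    expect_length(rcScan, 1)
    n <- nchar(text)
    expect_equal(IRanges::start(rcScan), n - IRanges::end(fwdScan) + 1L)
    expect_equal(IRanges::end(rcScan), n - IRanges::start(fwdScan) + 1L)
})

test_that("emitted candidates satisfy their structural invariants", {
    sim <- simulateGenome(simulationConfig(303, genomeLength = 4e5,
        families = defaultFamilies()[c(1, 3)], nOutwardDecoys = 4,
        nSingletons = 2, nNRich = 0))
    cands <- scanGenome(simGenome(sim), simQueries(sim))
    expect_gt(length(cands), 0)
    qs <- simQueries(sim)
    for (i in seq_along(cands)) {
        q <- qs[[S4Vectors::mcols(cands)$query_idx[i]]]
        expect_gte(IRanges::width(cands)[i], q@widthMin)
        expect_lte(IRanges::width(cands)[i], q@widthMax)
        expect_lte(S4Vectors::mcols(cands)$tsd_dist[i], q@tsdMismatch)
        expect_lte(S4Vectors::mcols(cands)$fwd_dist[i], q@tirMismatch)
        expect_lte(S4Vectors::mcols(cands)$rev_dist[i], q@tirMismatch)
    }
    # deduplicated: no overlapping candidates remain
    ov <- GenomicRanges::findOverlaps(cands, cands)
    expect_equal(length(ov), length(cands))
    expect_length(scanGenome(Biostrings::DNAStringSet(), qs), 0)
})
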