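test_that("classification applies thresholds and precedence strictly", {
    hit <- function(id, len, ev) {
        data.frame(qseqid = id, sseqid = "ref", pident = 95, length = len,
                   mismatch = 0, gapopen = 0, qstart = 1, qend = len,
                   sstart = 1, send = len, evalue = ev, bitscore = 100)
    }
    # transposase match beats a (better) CDS match
    expect_equal(classifyElements("e1", hit("e1", 300, 1e-6),
                                  hit("e1", 400, 1e-20)), "autonomous")
    expect_equal(classifyElements("e1", NULL, NULL), "non_pack")
    # strict inequalities: length must exceed the cutoff, E-value stay below
    expect_equal(classifyElements("e1", NULL, hit("e1", 50, 1e-6)), "non_pack")
    expect_equal(classifyElements("e1", NULL, hit("e1", 51, 1e-6)), "pack")
    expect_equal(classifyElements("e1", NULL, hit("e1", 400, 1e-5)), "non_pack")
    expect_equal(classifyElements("e1", hit("e1", 250, 1e-20), NULL), "non_pack")
    expect_equal(classifyElements("e1", hit("e1", 251, 1e-20), NULL), "autonomous")
    # extended-set style threshold
    expect_equal(classifyElements("e1", NULL, hit("e1", 200, 1e-9),
                                  cdsMinLen = 250), "non_pack")

    # monotone: adding hits never downgrades a category
    ranks <- c(non_pack = 1, pack = 2, autonomous = 3)
    base <- classifyElements("e1", NULL, hit("e1", 100, 1e-8))
    more <- classifyElements("e1", hit("e1", 300, 1e-8), hit("e1", 100, 1e-8))
    expect_gte(ranks[more], ranks[base])

    # categories partition the element set
    ids <- paste0("e", 1:4)
    cats <- classifyElements(ids, hit("e2", 300, 1e-8), hit("e3", 100, 1e-8))
    expect_equal(as.vector(table(factor(cats,
        c("autonomous", "pack", "non_pack")))), c(1L, 1L, 2L))
})

test_that("identifiers follow <prefix>-<superfamily>-<n> in genomic order", {
    gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(5000, 100, 900), width = 400))
    S4Vectors::mcols(gr)$superfamily <- c("CACTA", "CACTA", "CACTA")
    out <- assignIdentifiers(gr, "At")
    expect_equal(S4Vectors::mcols(out)$element_id,
                 c("At-CACTA-1", "At-CACTA-2", "At-CACTA-3"))
    expect_equal(IRanges::start(out), c(100L, 900L, 5000L))

    # numbering restarts per superfamily; rerun is deterministic
    S4Vectors::mcols(gr)$superfamily <- c("Mariner", "CACTA", "CACTA")
    out2 <- assignIdentifiers(gr, "Os")
    expect_equal(S4Vectors::mcols(out2)$element_id,
                 c("Os-CACTA-1", "Os-CACTA-2", "Os-Mariner-1"))
    expect_equal(S4Vectors::mcols(assignIdentifiers(gr, "Os"))$element_id,
                 S4Vectors::mcols(out2)$element_id)

    empty <- assignIdentifiers(gr[0], "At")
    expect_length(empty, 0)
})

test_that("internal similarity search finds planted fragments only", {
    set.seed(12)
    ref <- randSeq(800)
    db <- Biostrings::DNAStringSet(c(ref1 = ref, ref2 = randSeq(700)))
    frag <- substr(ref, 201, 500)
    elt <- Biostrings::DNAStringSet(c(
        carrier = paste0(randSeq(150), frag, randSeq(150)),
        carrier_rc = revComp(paste0(randSeq(150), frag, randSeq(150))),
        noise = randSeq(600)))
    hits <- runSimilaritySearch(elt, db, backend = "internal")
    carrier <- hits[hits$qseqid == "carrier" & hits$sseqid == "ref1", ]
    expect_gte(max(carrier$length), 300)
    expect_equal(max(carrier$pident), 100)
    expect_lt(min(carrier$evalue), 1e-5)
    # fragments on the minus strand are found too (sstart > send flags it)
    carrierRc <- hits[hits$qseqid == "carrier_rc" & hits$sseqid == "ref1", ]
    expect_gte(max(carrierRc$length), 300)
    expect_lt(min(carrierRc$evalue), 1e-5)
    expect_true(any(carrierRc$sstart > carrierRc$send))
    # unrelated sequence never passes the classification cutoff
    noise <- hits[hits$qseqid == "noise", ]
    expect_true(nrow(noise) == 0 || all(noise$evalue >= 1e-5))
    # empty database
    expect_equal(nrow(runSimilaritySearch(elt,
        Biostrings::DNAStringSet(), backend = "internal")), 0)
})

test_that("internal and external backends agree on element categories", {
    set.seed(23)
    tnp <- Biostrings::DNAStringSet(c(tnp1 = randSeq(600)))
    cds <- Biostrings::DNAStringSet(c(cds1 = randSeq(800)))
    elts <- Biostrings::DNAStringSet(c(
        auto = paste0(randSeq(100),
                      substr(as.character(tnp[[1]]), 101, 500), randSeq(100)),
        pack = paste0(randSeq(200),
                      substr(as.character(cds[[1]]), 301, 480), randSeq(200)),
        plain = randSeq(500)))
    catFor <- function(backend) {
        th <- runSimilaritySearch(elts, tnp, backend = backend)
        ch <- runSimilaritySearch(elts, cds, backend = backend)
        classifyElements(names(elts), th, ch)
    }
    internal <- catFor("internal")
    expect_equal(internal, c("autonomous", "pack", "non_pack"))
    expect_equal(catFor("external"), internal)
})

test_that("hit tables survive a write/read round trip", {
    hits <- data.frame(qseqid = "e1", sseqid = "s1", pident = 98.5,
                       length = 123L, mismatch = 2L, gapopen = 1L,
                       qstart = 10L, qend = 130L, sstart = 1L, send = 122L,
                       evalue = 3e-30, bitscore = 221.4)
    f <- withr::local_tempfile(fileext = ".tsv")
    write.table(hits, f, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    back <- readBlastTable(f)
    expect_equal(back, hits)
    writeLines(character(0), f)
    expect_equal(nrow(readBlastTable(f)), 0)
})
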