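# Independent oracles used to validate the implementation. These are written
# against base R (utils::adist) and plain arithmetic, never against the
# package's own code paths.

# Levenshtein distance where N mismatches everything (including N): map N to
# characters that can never match before calling adist.
oracleLev <- function(a, b) {
    a <- chartr("N", "!", toupper(a))
    b <- chartr("N", "?", toupper(b))
    as.integer(mapply(function(x, y) utils::adist(x, y), a, b))
}

# Exhaustive window enumeration: every (start, end) whose substring aligns to
# the seed within `budget` edits. Window lengths are limited to
# seed length +/- budget (any other length forces more than `budget` indels).
oracleTirMatches <- function(text, seed, budget) {
    n <- nchar(text)
    m <- nchar(seed)
    rows <- list()
    for (span in max(m - budget, 1):(m + budget)) {
        if (span > n) next
        starts <- seq_len(n - span + 1L)
        wins <- substring(text, starts, starts + span - 1L)
        d <- as.integer(utils::adist(chartr("N", "?", seed),
                                     chartr("N", "!", wins)))
        sel <- d <= budget
        if (any(sel))
            rows[[length(rows) + 1L]] <- data.frame(
                start = starts[sel], end = starts[sel] + span - 1L,
                dist = d[sel])
    }
    if (!length(rows)) {
        return(data.frame(start = integer(), end = integer(),
                          dist = integer()))
    }
    out <- unique(do.call(rbind, rows))
    out <- out[order(out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# Closed-form 2x2 chi-squared statistic and one-sided p (alternative
# p1 > p2), no continuity correction.
oracleOneSidedChi2 <- function(k1, n1, k2, n2) {
    a <- as.numeric(k1); b <- as.numeric(n1 - k1)
    c <- as.numeric(k2); d <- as.numeric(n2 - k2)
    n <- a + b + c + d
    stat <- n * (a * d - b * c)^2 /
        ((a + b) * (c + d) * (a + c) * (b + d))
    pTwo <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    if (k1 / n1 > k2 / n2) pTwo / 2 else 1 - pTwo / 2
}

# Jaccard-complement k-mer distance by explicit substring sets.
oracleKmerDist <- function(s1, s2, k) {
    kmers <- function(s) {
        if (nchar(s) < k) return(character(0))
        v <- substring(s, seq_len(nchar(s) - k + 1L),
                       seq_len(nchar(s) - k + 1L) + k - 1L)
        unique(v[!grepl("N", v)])
    }
    a <- kmers(s1); b <- kmers(s2)
    u <- union(a, b)
    if (!length(u)) return(0)
    1 - length(intersect(a, b)) / length(u)
}

randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A GRanges of candidate elements with attached sequences, for exercising
# the clustering stage without running a scan.
makeCands <- function(seqs, contig = "c1", gap = 500L) {
    lens <- nchar(seqs)
    starts <- cumsum(c(1L, utils::head(lens, -1) + gap))
    gr <- GenomicRanges::GRanges(contig,
        IRanges::IRanges(starts, width = lens))
    S4Vectors::mcols(gr)$seq <- as.character(seqs)
    S4Vectors::mcols(gr)$superfamily <- rep("Test", length(seqs))
    gr
}
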