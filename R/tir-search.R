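#' Levenshtein distance with wildcard-hostile N
#'
#' Elementwise edit distance (substitutions and indels cost 1). N mismatches
#' every base including another N: a conservative choice that keeps ambiguous
#' reference sequence from faking TIR or TSD agreement, complementing the
#' downstream N-content filter.
#'
#' @param a,b character vectors of equal length (or either of length 1).
#' @return integer vector of distances.
#' @examples
#' levDist("TA", "TC")
#' levDist("NN", "NN") # N never matches
#' @export
levDist <- function(a, b) {
    n <- max(length(a), length(b))
    a <- rep_len(toupper(a), n)
    b <- rep_len(toupper(b), n)
    cpp_lev(a, b)
}

# Expand the per-end-position DP minima into the complete set of qualifying
# windows: every (start, end) whose Levenshtein distance to the seed is
# within the budget. A TIR copy that diverged by indels admits several
# near-optimal spans whose boundaries differ by a base or two; committing to
# any single span here (leftmost, shortest, minimum-distance only, ...)
# systematically shifts the flush TSD window off the true flank for some
# planted configurations. Boundary ambiguity is instead resolved downstream:
# the TSD check discards spans whose flanks disagree and dedupCandidates()
# keeps one candidate per locus.
expandHitVariants <- function(hits, text, seed, budget) {
    if (nrow(hits) == 0L) return(hits)
    m <- nchar(seed)
    spans <- max(m - budget, 1L):(m + budget)
    out <- lapply(seq_len(nrow(hits)), function(i) {
        j <- hits$end[i]
        starts <- pmax(j - spans + 1L, 1L)
        wins <- substring(text, starts, j)
        d <- levDist(wins, seed)
        sel <- d <= budget
        data.frame(start = starts[sel], end = j, dist = d[sel])
    })
    out <- unique(do.call(rbind, out))
    out <- out[order(out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Find approximate TIR seed matches in a genome
#'
#' Semi-global matching: the seed is consumed in full while both ends are free
#' on the genome, so substitutions and indels each cost 1 and a hit's span can
#' deviate from the seed length by at most the budget. Every qualifying
#' window is returned -- equivalently, every genomic substring whose edit
#' distance to the seed is within the budget. Near-optimal spans of one
#' divergent TIR copy differ by a base or two at the boundaries; that
#' ambiguity is deliberately retained here and resolved downstream by TSD
#' verification and candidate deduplication.
#'
#' @param genome named `DNAStringSet` (or single character string).
#' @param seed TIR seed sequence (at least 6 nt).
#' @param maxMismatch Levenshtein budget; must be smaller than the seed
#'   length.
#' @return A `GRanges` sorted by (contig, start) with metadata column
#'   `edit_distance`.
#' @examples
#' g <- Biostrings::DNAStringSet(c(c1 = "TTCACTACAATT"))
#' findTirMatches(g, "CACTACAA", 0)
#' @export
findTirMatches <- function(genome, seed, maxMismatch = 0) {
    seed <- toupper(as.character(seed))
    if (nchar(seed) < 6L) stop("seed must be at least 6 nt")
    maxMismatch <- as.integer(maxMismatch)
    if (maxMismatch >= nchar(seed)) stop("budget must be smaller than the seed length")
    if (is.character(genome)) {
        genome <- Biostrings::DNAStringSet(genome)
        if (is.null(names(genome))) names(genome) <- paste0("contig", seq_along(genome))
    }
    res <- lapply(names(genome), function(ctg) {
        text <- as.character(genome[[ctg]])
        hits <- cpp_semiglobal_scan(text, seed, maxMismatch)
        hits <- expandHitVariants(hits, text, seed, maxMismatch)
        if (nrow(hits) == 0L) return(NULL)
        GenomicRanges::GRanges(ctg, IRanges::IRanges(hits$start, hits$end),
                               edit_distance = hits$dist)
    })
    res <- res[!vapply(res, is.null, logical(1))]
    if (!length(res)) {
        return(GenomicRanges::GRanges(edit_distance = integer()))
    }
    out <- do.call(c, res)
    out[order(as.character(GenomicRanges::seqnames(out)), IRanges::start(out))]
}

#' Pair forward and reverse TIR matches into candidate elements
#'
#' Emits every inward-facing pair (forward-seed match upstream of a
#' reverse-seed match on the same contig) whose overall width falls in the
#' query's window. Nested and overlapping pairings are all emitted here and
#' resolved later by [dedupCandidates()].
#'
#' @param fwd,rev `GRanges` of forward-seed and reverse-seed matches
#'   (from [findTirMatches()]).
#' @param query the [TirQuery-class] the matches derive from.
#' @return A `GRanges` of TSD-unchecked candidates with metadata columns
#'   `superfamily`, `fwd_start`, `fwd_end`, `fwd_dist`, `rev_start`,
#'   `rev_end`, `rev_dist`.
#' @export
pairCandidates <- function(fwd, rev, query) {
    empty <- GenomicRanges::GRanges(
        superfamily = character(), fwd_start = integer(), fwd_end = integer(),
        fwd_dist = integer(), rev_start = integer(), rev_end = integer(),
        rev_dist = integer())
    if (length(fwd) == 0L || length(rev) == 0L) return(empty)
    # width = rev_end - fwd_start + 1 within [widthMin, widthMax]
    windows <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(fwd),
        IRanges::IRanges(IRanges::start(fwd) + query@widthMin - 1L,
                         IRanges::start(fwd) + query@widthMax - 1L))
    revEnds <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(rev),
        IRanges::IRanges(IRanges::end(rev), IRanges::end(rev)))
    ov <- GenomicRanges::findOverlaps(revEnds, windows)
    if (length(ov) == 0L) return(empty)
    f <- S4Vectors::subjectHits(ov)
    r <- S4Vectors::queryHits(ov)
    keep <- IRanges::start(rev)[r] > IRanges::start(fwd)[f]
    f <- f[keep]; r <- r[keep]
    if (!length(f)) return(empty)
    GenomicRanges::GRanges(
        GenomicRanges::seqnames(fwd)[f],
        IRanges::IRanges(IRanges::start(fwd)[f], IRanges::end(rev)[r]),
        superfamily = rep(query@superfamily, length(f)),
        fwd_start = IRanges::start(fwd)[f], fwd_end = IRanges::end(fwd)[f],
        fwd_dist = S4Vectors::mcols(fwd)$edit_distance[f],
        rev_start = IRanges::start(rev)[r], rev_end = IRanges::end(rev)[r],
        rev_dist = S4Vectors::mcols(rev)$edit_distance[r])
}

#' Verify target site duplications on candidate elements
#'
#' Extracts the `tsdLength` bases immediately flanking each candidate and
#' keeps the candidate iff the Levenshtein distance between the two flanks is
#' within the query's TSD budget. Candidates flush with a contig edge have no
#' flank and are rejected (the TSD filter is mandatory). When the query
#' specifies a fixed motif, whether the 5' TSD equals it is recorded (for
#' composition summaries) but filtering stays flank-vs-flank.
#'
#' @param genome `DNAStringSet`.
#' @param cands candidate `GRanges` from [pairCandidates()].
#' @param query the generating [TirQuery-class].
#' @return The surviving candidates with metadata columns `tsd_5`, `tsd_3`,
#'   `tsd_dist` (and `tsd_motif_match` for motif queries) added.
#' @export
checkTsd <- function(genome, cands, query) {
    len <- query@tsdLength
    if (length(cands) == 0L || len == 0L) {
        if (length(cands)) {
            S4Vectors::mcols(cands)$tsd_5 <- rep("", length(cands))
            S4Vectors::mcols(cands)$tsd_3 <- rep("", length(cands))
            S4Vectors::mcols(cands)$tsd_dist <- rep(0L, length(cands))
        }
        return(cands)
    }
    contigs <- as.character(GenomicRanges::seqnames(cands))
    clen <- Biostrings::width(genome)[match(contigs, names(genome))]
    atEdge <- IRanges::start(cands) - len < 1L | IRanges::end(cands) + len > clen
    if (any(atEdge)) {
        message(sum(atEdge), " candidate(s) rejected: flush with contig edge, ",
                "no flank for TSD verification")
        cands <- cands[!atEdge]
        contigs <- contigs[!atEdge]
    }
    if (length(cands) == 0L) return(cands)
    tsd5 <- vapply(seq_along(cands), function(i) {
        as.character(Biostrings::subseq(genome[[contigs[i]]],
            IRanges::start(cands)[i] - len, IRanges::start(cands)[i] - 1L))
    }, character(1))
    tsd3 <- vapply(seq_along(cands), function(i) {
        as.character(Biostrings::subseq(genome[[contigs[i]]],
            IRanges::end(cands)[i] + 1L, IRanges::end(cands)[i] + len))
    }, character(1))
    d <- levDist(tsd5, tsd3)
    keep <- d <= query@tsdMismatch
    cands <- cands[keep]
    S4Vectors::mcols(cands)$tsd_5 <- tsd5[keep]
    S4Vectors::mcols(cands)$tsd_3 <- tsd3[keep]
    S4Vectors::mcols(cands)$tsd_dist <- d[keep]
    if (!is.na(query@tsdMotif))
        S4Vectors::mcols(cands)$tsd_motif_match <- tsd5[keep] == query@tsdMotif
    cands
}

#' Remove duplicated and overlapping candidates
#'
#' Multiple TIR queries (and nested pairings from a single query) can describe
#' the same locus more than once, inflating element counts. Among any set of
#' candidates whose genomic spans overlap, exactly one survives: the widest,
#' ties broken by leftmost start, then by query order.
#'
#' @param cands candidate `GRanges`; a `query_idx` metadata column, when
#'   present, supplies the query-order tie-break.
#' @return The surviving candidates sorted by (contig, start).
#' @export
dedupCandidates <- function(cands) {
    if (length(cands) <= 1L) return(cands)
    qidx <- S4Vectors::mcols(cands)$query_idx
    if (is.null(qidx)) qidx <- seq_along(cands)
    o <- order(as.character(GenomicRanges::seqnames(cands)),
               IRanges::start(cands), IRanges::end(cands))
    cands <- cands[o]; qidx <- qidx[o]
    ctg <- as.character(GenomicRanges::seqnames(cands))
    newGrp <- c(TRUE, ctg[-1] != ctg[-length(ctg)] |
                IRanges::start(cands)[-1] >
                    cummaxPerContig(IRanges::end(cands), ctg)[-length(ctg)])
    grp <- cumsum(newGrp)
    pick <- vapply(split(seq_along(cands), grp), function(ix) {
        w <- IRanges::width(cands)[ix]
        ix <- ix[w == max(w)]
        s <- IRanges::start(cands)[ix]
        ix <- ix[s == min(s)]
        ix[which.min(qidx[ix])]
    }, integer(1))
    cands[sort(pick)]
}

# running max of `end` that resets at contig boundaries
cummaxPerContig <- function(ends, ctg) {
    unlist(lapply(split(ends, factor(ctg, levels = unique(ctg))), cummax),
           use.names = FALSE)
}

#' Scan a genome for candidate Pack-TYPE elements (pipeline step 1)
#'
#' For each query: find approximate matches of the forward and reverse TIR
#' seeds, pair them into inward-facing candidates within the width window,
#' verify TSDs, and deduplicate; the per-query results are then merged and
#' deduplicated again across queries. Deterministic for fixed inputs.
#'
#' @param genome named `DNAStringSet`.
#' @param queries a [TirQuery-class] or list of them.
#' @return A `GRanges` of candidates sorted by (contig, start), with element
#'   sequences in the `seq` metadata column.
#' @export
scanGenome <- function(genome, queries) {
    if (is(queries, "TirQuery")) queries <- list(queries)
    if (length(queries) < 1L) stop("at least one query is required")
    perQuery <- lapply(seq_along(queries), function(qi) {
        q <- queries[[qi]]
        fwd <- findTirMatches(genome, q@fwdTir, q@tirMismatch)
        rev <- findTirMatches(genome, q@revTir, q@tirMismatch)
        cands <- pairCandidates(fwd, rev, q)
        cands <- checkTsd(genome, cands, q)
        if (length(cands)) {
            S4Vectors::mcols(cands)$query_idx <- rep(qi, length(cands))
            if (is.null(S4Vectors::mcols(cands)$tsd_motif_match))
                S4Vectors::mcols(cands)$tsd_motif_match <- rep(NA, length(cands))
            cands <- dedupCandidates(cands)
        }
        cands
    })
    perQuery <- perQuery[vapply(perQuery, length, integer(1)) > 0L]
    if (!length(perQuery)) {
        return(GenomicRanges::GRanges(
            superfamily = character(), fwd_start = integer(),
            fwd_end = integer(), fwd_dist = integer(), rev_start = integer(),
            rev_end = integer(), rev_dist = integer(), tsd_5 = character(),
            tsd_3 = character(), tsd_dist = integer(),
            tsd_motif_match = logical(), query_idx = integer(),
            seq = character()))
    }
    merged <- suppressWarnings(do.call(c, perQuery))
    merged <- dedupCandidates(merged)
    S4Vectors::mcols(merged)$seq <-
        as.character(extractElementSeqs(merged, genome))
    merged
}
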