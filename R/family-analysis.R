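#' Alignment-free TIR distance matrix
#'
#' Takes the first `prefixLen` bases of each (forward-oriented) element --
#' covering the forward TIR and adjacent subterminal sequence -- and computes
#' pairwise distances as the Jaccard complement on the sets of distinct
#' k-mers: `1 - |shared| / |union|`. k-mers containing N are ignored.
#'
#' @param seqs named character vector or `DNAStringSet` of element sequences,
#'   oriented forward per the cluster convention.
#' @param prefixLen prefix length in bp (default 80); shorter sequences are
#'   used in full with a warning.
#' @param k k-mer size (default 5).
#' @return symmetric distance matrix with zero diagonal, dimnames from the
#'   sequence names.
#' @export
tirDistanceMatrix <- function(seqs, prefixLen = 80, k = 5) {
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    if (is.null(names(seqs))) names(seqs) <- paste0("e", seq_along(seqs))
    short <- Biostrings::width(seqs) < prefixLen
    if (any(short))
        warning(sum(short), " sequence(s) shorter than ", prefixLen,
                " bp; used in full")
    pre <- Biostrings::subseq(seqs, 1, pmin(Biostrings::width(seqs), prefixLen))
    counts <- Biostrings::oligonucleotideFrequency(pre, width = k)
    present <- counts > 0
    shared <- tcrossprod(present * 1)
    sizes <- rowSums(present)
    un <- outer(sizes, sizes, "+") - shared
    d <- 1 - shared / un
    d[un == 0] <- 0 # two empty k-mer sets: treat as indistinguishable
    diag(d) <- 0
    dimnames(d) <- list(names(seqs), names(seqs))
    d
}

#' Cut a complete-linkage dendrogram of TIR distances
#'
#' Orders elements by complete-linkage hierarchical clustering of the TIR
#' distance matrix and cuts the dendrogram into `nGroups` groups. Rows are
#' sorted by id before clustering so the result does not depend on input
#' order.
#'
#' @param d distance matrix from [tirDistanceMatrix()].
#' @param nGroups number of groups to cut into (default 6).
#' @return list with `groups` (named integer vector) and `order` (leaf order
#'   of the dendrogram, as ids).
#' @export
clusterTirMatrix <- function(d, nGroups = 6) {
    stopifnot(is.matrix(d), nrow(d) == ncol(d))
    if (nGroups > nrow(d)) stop("nGroups exceeds the number of elements")
    ids <- sort(rownames(d))
    d <- d[ids, ids]
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    groups <- stats::cutree(hc, k = nGroups)
    list(groups = groups, order = ids[hc$order], hclust = hc)
}

#' Find pairs of elements within a genomic window
#'
#' All unordered same-contig pairs whose gap (distance between closest ends;
#' 0 if they overlap) is at most `window`, flagged by whether the two
#' elements share a cluster and an orientation.
#'
#' @param records element `GRanges` with metadata columns `element_id`,
#'   `cluster_id` and strand set.
#' @param window maximum gap in bp (default 100000).
#' @return data.frame with columns `element_a`, `element_b`, `distance`,
#'   `same_cluster`, `same_orientation`.
#' @export
findLocalPairs <- function(records, window = 1e5) {
    empty <- data.frame(element_a = character(), element_b = character(),
                        distance = integer(), same_cluster = logical(),
                        same_orientation = logical())
    if (length(records) < 2L) return(empty)
    ext <- GenomicRanges::resize(GenomicRanges::granges(records),
                                 IRanges::width(records) + 2 * window,
                                 fix = "center")
    ov <- GenomicRanges::findOverlaps(GenomicRanges::granges(records), ext,
                                      ignore.strand = TRUE)
    a <- S4Vectors::queryHits(ov)
    b <- S4Vectors::subjectHits(ov)
    keep <- a < b
    a <- a[keep]; b <- b[keep]
    if (!length(a)) return(empty)
    dist <- GenomicRanges::distance(records[a], records[b],
                                    ignore.strand = TRUE)
    keep <- !is.na(dist) & dist <= window
    a <- a[keep]; b <- b[keep]; dist <- dist[keep]
    if (!length(a)) return(empty)
    mc <- S4Vectors::mcols(records)
    data.frame(
        element_a = mc$element_id[a],
        element_b = mc$element_id[b],
        distance = as.integer(dist),
        same_cluster = mc$cluster_id[a] == mc$cluster_id[b],
        same_orientation = as.character(GenomicRanges::strand(records))[a] ==
            as.character(GenomicRanges::strand(records))[b])
}

# 2x2 chi-squared (no continuity correction) converted to a one-sided
# p-value for the alternative p1 > p2. Table rows: (local, not local) for
# members and for non-members.
.oneSidedChi2 <- function(k1, n1, k2, n2) {
    if (n1 == 0 || n2 == 0)
        return(list(p = 1, statistic = NA_real_, flag = "degenerate"))
    tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        return(list(p = 1, statistic = NA_real_, flag = "degenerate"))
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - e)^2 / e)
    pTwo <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    p <- if (k1 / n1 > k2 / n2) pTwo / 2 else 1 - pTwo / 2
    list(p = p, statistic = stat, flag = NA_character_)
}

#' One-sided test for local hopping
#'
#' Class II transposons tend to reinsert near their donor locus, so members
#' of a family should lie within `window` of another family member more often
#' than unrelated elements do. For each cluster the proportion of members
#' with a cluster-mate within the window is compared to the proportion of
#' non-members within the window of a member, by a one-sided chi-squared test
#' on the 2x2 counts (no continuity correction). With
#' `superfamily` given, the 2x2 counts are pooled over all clusters of that
#' superfamily before testing.
#'
#' @param records element `GRanges` with `element_id`, `cluster_id`,
#'   `superfamily` metadata.
#' @param clusterId cluster to test (ignored when `superfamily` is given).
#' @param superfamily pool counts across all clusters (of size >= 2) of this
#'   superfamily.
#' @param window distance window in bp (default 100000).
#' @return list with `p`, `statistic`, `counts` (the pooled 2x2 entries
#'   `k1`, `n1`, `k2`, `n2`) and `flag`.
#' @export
localHoppingTest <- function(records, clusterId = NULL, superfamily = NULL,
                             window = 1e5) {
    mc <- S4Vectors::mcols(records)
    clusters <- if (!is.null(superfamily)) {
        cl <- unique(mc$cluster_id[mc$superfamily == superfamily])
        cl[vapply(cl, function(k) sum(mc$cluster_id == k) >= 2L, logical(1))]
    } else {
        if (is.null(clusterId)) stop("give either clusterId or superfamily")
        clusterId
    }
    if (!length(clusters)) stop("no clusters of size >= 2 to test")
    k1 <- n1 <- k2 <- n2 <- 0L
    for (cid in clusters) {
        mem <- which(mc$cluster_id == cid)
        non <- which(mc$cluster_id != cid)
        if (length(mem) < 2L || length(non) < 1L)
            stop("cluster must have >= 2 members and >= 1 non-member")
        memGr <- records[mem]
        d <- GenomicRanges::distance
        memLocal <- vapply(seq_along(mem), function(i) {
            dd <- d(memGr[i], memGr[-i], ignore.strand = TRUE)
            any(!is.na(dd) & dd <= window)
        }, logical(1))
        nonLocal <- vapply(non, function(j) {
            dd <- d(records[j], memGr, ignore.strand = TRUE)
            any(!is.na(dd) & dd <= window)
        }, logical(1))
        k1 <- k1 + sum(memLocal); n1 <- n1 + length(memLocal)
        k2 <- k2 + sum(nonLocal); n2 <- n2 + length(nonLocal)
    }
    res <- .oneSidedChi2(k1, n1, k2, n2)
    res$counts <- c(k1 = k1, n1 = n1, k2 = k2, n2 = n2)
    res
}

#' Orientation concordance of local same-cluster pairs
#'
#' Among local pairs belonging to the same cluster, the fraction inserted in
#' the same orientation on the chromosome.
#'
#' @param pairs data.frame from [findLocalPairs()].
#' @return fraction in \[0, 1\], or `NA` (with a message) when there are no
#'   same-cluster pairs.
#' @examples
#' orientationConcordance(data.frame(same_cluster = rep(TRUE, 15),
#'                                   same_orientation = rep(c(TRUE, FALSE),
#'                                                          c(12, 3))))
#' @export
orientationConcordance <- function(pairs) {
    pairs <- pairs[pairs$same_cluster, , drop = FALSE]
    if (nrow(pairs) == 0L) {
        message("no same-cluster local pairs; concordance undefined")
        return(NA_real_)
    }
    mean(pairs$same_orientation)
}

#' TSD composition summary
#'
#' The fraction of elements whose 5' TSD equals a motif, together with the
#' full TSD frequency table.
#'
#' @param records element `GRanges` with a `tsd_5` metadata column (or a
#'   [PackTESet-class]).
#' @param motif motif to match exactly, e.g. `"TA"`.
#' @return list with `fraction` and `table`.
#' @export
tsdComposition <- function(records, motif) {
    if (is(records, "PackTESet")) records <- teRanges(records)
    tsd <- S4Vectors::mcols(records)$tsd_5
    if (is.null(tsd)) stop("records carry no tsd_5 column")
    list(fraction = if (length(tsd)) mean(tsd == toupper(motif)) else NA_real_,
         table = sort(table(tsd), decreasing = TRUE))
}
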