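#' Filter candidates on wildcard (N) content
#'
#' Assemblies pad uncertain regions with N; alignments over such sequence are
#' unreliable, so elements whose sequence is more than `maxFrac` N are
#' removed. The threshold is strict: a fraction exactly equal to `maxFrac`
#' (e.g. 10%) is kept.
#'
#' @param cands candidate `GRanges` with a `seq` metadata column.
#' @param maxFrac maximum tolerated N fraction (default 0.10).
#' @return The surviving candidates.
#' @export
filterNContent <- function(cands, maxFrac = 0.10) {
    if (length(cands) == 0L) return(cands)
    seqs <- S4Vectors::mcols(cands)$seq
    if (is.null(seqs)) stop("candidates carry no sequences; run scanGenome()")
    nN <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seqs))[, "N"]
    cands[nN / IRanges::width(cands) <= maxFrac]
}

# Global pairwise identity (matching columns / alignment columns), maximised
# over the two strands of `b`. Scoring: match +1, mismatch -1, affine gaps
# (opening 10, extension 4) so that unrelated sequences do not inflate their
# identity through liberal gapping.
.pairIdentity <- function(a, b) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE)
    idOne <- function(x, y) {
        aln <- Biostrings::pairwiseAlignment(
            x, y, type = "global", substitutionMatrix = mat,
            gapOpening = 10, gapExtension = 4)
        Biostrings::nmatch(aln) / Biostrings::nchar(aln)
    }
    max(idOne(a, b), idOne(a, revComp(b)))
}

#' Group candidate elements into families by greedy centroid clustering
#'
#' Candidates are processed in decreasing width order (ties by contig then
#' start); each joins the first existing centroid whose pairwise global
#' identity -- matching columns over alignment columns, computed on the better
#' of the two strands -- reaches the threshold, otherwise it founds a new
#' centroid. The ordering makes the procedure deterministic and independent
#' of input shuffling.
#'
#' @param cands candidate `GRanges` with sequences (`seq` column).
#' @param identityThreshold minimum identity for cluster membership
#'   (default 0.60).
#' @return `cands` with an integer `cluster_id` metadata column (numbered in
#'   order of centroid foundation).
#' @export
clusterElements <- function(cands, identityThreshold = 0.60) {
    if (length(cands) == 0L) return(cands)
    seqs <- S4Vectors::mcols(cands)$seq
    if (is.null(seqs)) stop("candidates carry no sequences; run scanGenome()")
    ord <- order(-IRanges::width(cands),
                 as.character(GenomicRanges::seqnames(cands)),
                 IRanges::start(cands))
    centroidIdx <- integer(0)
    assign <- integer(length(cands))
    for (i in ord) {
        placed <- FALSE
        for (ci in seq_along(centroidIdx)) {
            if (.pairIdentity(seqs[i], seqs[centroidIdx[ci]]) >= identityThreshold) {
                assign[i] <- ci
                placed <- TRUE
                break
            }
        }
        if (!placed) {
            centroidIdx <- c(centroidIdx, i)
            assign[i] <- length(centroidIdx)
        }
    }
    S4Vectors::mcols(cands)$cluster_id <- assign
    cands
}

#' Drop singleton clusters
#'
#' Genuine transposable elements are repeated in the genome, so a family of
#' size one is treated as a likely false positive and removed. Surviving
#' clusters are renumbered 1..K in decreasing size, ties by first genomic
#' occurrence.
#'
#' @param cands clustered `GRanges` (with `cluster_id`).
#' @return The candidates belonging to clusters of size >= 2, with
#'   `cluster_id` renumbered.
#' @export
removeSingletons <- function(cands) {
    if (length(cands) == 0L) return(cands)
    cl <- S4Vectors::mcols(cands)$cluster_id
    if (is.null(cl)) stop("candidates are not clustered; run clusterElements()")
    sizes <- table(cl)
    keep <- cl %in% as.integer(names(sizes)[sizes >= 2L])
    cands <- cands[keep]
    cl <- cl[keep]
    if (length(cands) == 0L) return(cands)
    # renumber: decreasing size, ties by first genomic occurrence
    genomicRank <- order(order(as.character(GenomicRanges::seqnames(cands)),
                               IRanges::start(cands)))
    firstOcc <- vapply(split(genomicRank, cl), min, integer(1))
    size <- vapply(split(cl, cl), length, integer(1))
    ids <- as.integer(names(firstOcc))
    newOrder <- ids[order(-size, firstOcc)]
    S4Vectors::mcols(cands)$cluster_id <- match(cl, newOrder)
    cands
}

#' Assign per-member orientation within clusters
#'
#' The orientation of a non-autonomous element cannot be defined from its own
#' sequence, so the largest element of each cluster is arbitrarily taken as
#' forward ("+") and every other member receives the strand on which its
#' alignment to that representative scores the higher identity (exact ties
#' stay "+").
#'
#' @param cands clustered `GRanges` (singletons already removed).
#' @return `cands` with strand set and a logical `representative` metadata
#'   column marking each cluster's largest member.
#' @export
assignOrientation <- function(cands) {
    if (length(cands) == 0L) return(cands)
    cl <- S4Vectors::mcols(cands)$cluster_id
    seqs <- S4Vectors::mcols(cands)$seq
    strand <- rep("+", length(cands))
    isRep <- rep(FALSE, length(cands))
    mat <- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE)
    idOne <- function(x, y) {
        aln <- Biostrings::pairwiseAlignment(
            x, y, type = "global", substitutionMatrix = mat,
            gapOpening = 10, gapExtension = 4)
        Biostrings::nmatch(aln) / Biostrings::nchar(aln)
    }
    for (k in unique(cl)) {
        ix <- which(cl == k)
        # representative: maximum width, ties by genomic position
        o <- ix[order(-IRanges::width(cands)[ix],
                      as.character(GenomicRanges::seqnames(cands))[ix],
                      IRanges::start(cands)[ix])]
        rep_i <- o[1]
        isRep[rep_i] <- TRUE
        for (i in setdiff(ix, rep_i)) {
            fwdId <- idOne(seqs[i], seqs[rep_i])
            revId <- idOne(revComp(seqs[i]), seqs[rep_i])
            if (revId > fwdId) strand[i] <- "-"
        }
    }
    GenomicRanges::strand(cands) <- strand
    S4Vectors::mcols(cands)$representative <- isRep
    cands
}

#' Cluster membership table
#'
#' Flat per-member view of the clustering: cluster id, size, representative,
#' member id and orientation, suitable for writing as TSV.
#'
#' @param x a [PackTESet-class] or clustered element `GRanges`.
#' @return data.frame with columns `cluster_id`, `size`,
#'   `representative_id`, `member_id`, `orientation`.
#' @export
clusterTable <- function(x) {
    gr <- if (is(x, "PackTESet")) teRanges(x) else x
    mc <- S4Vectors::mcols(gr)
    if (is.null(mc$cluster_id)) stop("elements are not clustered")
    size <- as.integer(table(mc$cluster_id)[as.character(mc$cluster_id)])
    repId <- vapply(mc$cluster_id, function(k) {
        ix <- which(mc$cluster_id == k)
        ix <- ix[order(-IRanges::width(gr)[ix], IRanges::start(gr)[ix])]
        mc$element_id[ix[1]]
    }, "")
    out <- data.frame(cluster_id = mc$cluster_id, size = size,
                      representative_id = repId, member_id = mc$element_id,
                      orientation = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
    out[order(out$cluster_id, out$member_id), ]
}
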