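#' Sensitivity of element recovery
#'
#' The fraction of known elements recovered:
#' `identified / total_known`.
#'
#' @param identified number of known elements identified.
#' @param totalKnown total number of known elements (> 0).
#' @return fraction in \[0, 1\].
#' @examples
#' computeSensitivity(2068, 2776)
#' @export
computeSensitivity <- function(identified, totalKnown) {
    if (totalKnown <= 0) stop("totalKnown must be positive")
    if (identified < 0 || identified > totalKnown)
        stop("identified must lie in [0, totalKnown]")
    identified / totalKnown
}

#' False-positive rate from the reversed-TIR decoy search
#'
#' Outward-facing TIR pairs are unlikely to delimit a genuine element, so the
#' number of candidates recovered after swapping the forward and reverse TIR
#' seeds estimates the rate of chance matches:
#' `1 - specificity = reversed / correct`.
#' The raw ratio is returned (it can exceed 1 on pathological inputs);
#' [rocAuc()] clamps it to 1 for plotting/integration.
#'
#' @param reversedCount candidates found with swapped seeds.
#' @param correctCount candidates found with correct seeds (> 0).
#' @return the raw ratio.
#' @export
computeFpr <- function(reversedCount, correctCount) {
    if (correctCount <= 0) stop("correctCount must be positive; FPR undefined")
    reversedCount / correctCount
}

#' Count candidates found with reversed TIR seeds
#'
#' Repeats the first pipeline step with the forward TIRs used as reverse TIRs
#' and vice versa, so the search returns outward-facing TIR pairs. No
#' clustering or classification is applied.
#'
#' @param genome `DNAStringSet`.
#' @param queries [TirQuery-class] or list of them.
#' @return integer candidate count.
#' @export
reversedTirScan <- function(genome, queries) {
    if (is(queries, "TirQuery")) queries <- list(queries)
    swapped <- lapply(queries, function(q) {
        s <- q
        s@fwdTir <- q@revTir
        s@revTir <- q@fwdTir
        s
    })
    length(scanGenome(genome, swapped))
}

#' Area under an ROC curve by trapezoidal integration
#'
#' Points are sorted by false-positive rate (clamped to \[0, 1\]); the
#' anchors (0,0) and (1,1) are appended if absent.
#'
#' @param points data.frame with columns `fpr` and `sensitivity` (at least
#'   two rows).
#' @return AUC in \[0, 1\].
#' @examples
#' rocAuc(data.frame(fpr = c(0, 0, 1), sensitivity = c(0, 1, 1))) # perfect
#' @export
rocAuc <- function(points) {
    stopifnot(is.data.frame(points),
              all(c("fpr", "sensitivity") %in% names(points)))
    if (nrow(points) < 2L) stop("at least two ROC points are required")
    x <- pmin(pmax(points$fpr, 0), 1)
    y <- points$sensitivity
    if (!any(x == 0 & y == 0)) { x <- c(0, x); y <- c(0, y) }
    if (!any(x == 1 & y == 1)) { x <- c(x, 1); y <- c(y, 1) }
    o <- order(x, y)
    x <- x[o]; y <- y[o]
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Match predictions against a truth annotation
#'
#' A prediction matches a truth element iff their reciprocal overlap (shared
#' bases over the length of the longer of the two) reaches the threshold;
#' matching is one-to-one and greedy by descending overlap. The overlap
#' criterion is exposed because published benchmarks rarely state one.
#'
#' @param predicted,truth `GRanges` on the same genome.
#' @param minReciprocalOverlap minimum reciprocal overlap (default 0.5).
#' @return list with `recall`, `precision`, `matched` (data.frame of matched
#'   index pairs and their overlap) and `flag` (`"no_predictions"` when the
#'   prediction set is empty, in which case precision is reported as 0).
#' @export
evaluateAgainstTruth <- function(predicted, truth, minReciprocalOverlap = 0.5) {
    if (length(truth) == 0L) stop("truth set is empty")
    if (length(predicted) == 0L) {
        return(list(recall = 0, precision = 0,
                    matched = data.frame(pred = integer(), truth = integer(),
                                         overlap = numeric()),
                    flag = "no_predictions"))
    }
    ov <- GenomicRanges::findOverlaps(predicted, truth, ignore.strand = TRUE)
    p <- S4Vectors::queryHits(ov)
    t <- S4Vectors::subjectHits(ov)
    inter <- IRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(predicted)[p], GenomicRanges::ranges(truth)[t]))
    recip <- inter / pmax(IRanges::width(predicted)[p],
                          IRanges::width(truth)[t])
    keep <- recip >= minReciprocalOverlap
    p <- p[keep]; t <- t[keep]; recip <- recip[keep]
    o <- order(-recip, p, t)
    usedP <- logical(length(predicted))
    usedT <- logical(length(truth))
    mp <- integer(0); mt <- integer(0); mo <- numeric(0)
    for (i in o) {
        if (!usedP[p[i]] && !usedT[t[i]]) {
            usedP[p[i]] <- TRUE
            usedT[t[i]] <- TRUE
            mp <- c(mp, p[i]); mt <- c(mt, t[i]); mo <- c(mo, recip[i])
        }
    }
    list(recall = length(mt) / length(truth),
         precision = length(mp) / length(predicted),
         matched = data.frame(pred = mp, truth = mt, overlap = mo),
         flag = NA_character_)
}

#' ROC sweep over TIR mismatch budgets
#'
#' For each budget, the first pipeline step is run with the TIR budget set to
#' that value (TSD budget fixed, default 2, mirroring the observation that
#' two TSD mismatches suffice) on every genome of the input; sensitivity is
#' measured against the planted/known truth and the false-positive rate from
#' the reversed-seed search.
#'
#' @param sims a [PackSimulation-class], or list of them (e.g. from
#'   [gradeDivergenceSeries()]); alternatively a list of lists with entries
#'   `genome`, `truth`, `queries`.
#' @param budgets integer vector of TIR mismatch budgets (default 0:10 where
#'   the seed length allows).
#' @param tsdMismatch fixed TSD budget for the sweep (default 2).
#' @param minReciprocalOverlap matching threshold (default 0.5).
#' @return data.frame with columns `tir_mismatch`, `identified`, `total`,
#'   `correct`, `reversed`, `sensitivity`, `fpr`.
#' @export
rocSweep <- function(sims, budgets = 0:10, tsdMismatch = 2,
                     minReciprocalOverlap = 0.5) {
    if (is(sims, "PackSimulation")) sims <- list(sims)
    norm <- lapply(sims, function(s) {
        if (is.list(s) && !is.null(s$sim)) s <- s$sim # divergence-series entry
        if (is(s, "PackSimulation")) {
            tr <- s@truth
            tr <- tr[S4Vectors::mcols(tr)$role %in% c("member", "singleton")]
            list(genome = s@genome, truth = tr, queries = s@queries)
        } else s
    })
    rows <- lapply(budgets, function(b) {
        identified <- 0L; total <- 0L; correct <- 0L; reversed <- 0L
        for (s in norm) {
            qs <- lapply(s$queries, function(q) {
                q@tirMismatch <- as.integer(min(b, nchar(q@fwdTir) - 1L))
                q@tsdMismatch <- as.integer(tsdMismatch)
                q
            })
            pred <- scanGenome(s$genome, qs)
            ev <- evaluateAgainstTruth(pred, s$truth, minReciprocalOverlap)
            identified <- identified + nrow(ev$matched)
            total <- total + length(s$truth)
            correct <- correct + length(pred)
            reversed <- reversed + reversedTirScan(s$genome, qs)
        }
        data.frame(tir_mismatch = b, identified = identified, total = total,
                   correct = correct, reversed = reversed,
                   sensitivity = identified / total,
                   fpr = if (correct > 0) reversed / correct else NA_real_)
    })
    do.call(rbind, rows)
}
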