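#' TIR search query
#'
#' Bundles one superfamily's search parameters: the forward TIR seed, the
#' reverse seed (by default the reverse complement of the forward seed), the
#' Levenshtein budgets for TIR and TSD matching, the TSD length or fixed
#' motif, and the element width window.
#'
#' @slot superfamily single character label, e.g. \code{"CACTA"}.
#' @slot fwdTir forward TIR seed (8--30 nt works well; at least 6 nt).
#' @slot revTir reverse TIR seed; defaults to the reverse complement of
#'   \code{fwdTir}.
#' @slot tirMismatch maximum Levenshtein distance allowed for a TIR match.
#' @slot tsdLength expected TSD length in bp.
#' @slot tsdMotif optional fixed TSD motif (e.g. \code{"TA"} for Mariner).
#'   When given, \code{tsdLength} defaults to its width and elements record
#'   whether their 5' TSD equals the motif; filtering remains flank-vs-flank.
#' @slot tsdMismatch maximum Levenshtein distance between the 5' and 3'
#'   flanks.
#' @slot widthMin,widthMax element width window in bp (defaults 300 and
#'   15000).
#'
#' @export
setClass("TirQuery",
    slots = c(
        superfamily = "character",
        fwdTir = "character",
        revTir = "character",
        tirMismatch = "integer",
        tsdLength = "integer",
        tsdMotif = "character",
        tsdMismatch = "integer",
        widthMin = "integer",
        widthMax = "integer"
    )
)

setValidity("TirQuery", function(object) {
    msg <- character()
    ok1 <- function(x) length(x) == 1L && !is.na(x)
    if (!ok1(object@superfamily)) msg <- c(msg, "superfamily must be a single string")
    if (!ok1(object@fwdTir) || nchar(object@fwdTir) < 6L)
        msg <- c(msg, "fwdTir must be a single seed of at least 6 nt")
    if (!ok1(object@revTir) || nchar(object@revTir) < 6L)
        msg <- c(msg, "revTir must be a single seed of at least 6 nt")
    if (ok1(object@fwdTir) && grepl("[^ACGTN]", object@fwdTir))
        msg <- c(msg, "fwdTir must use the A,C,G,T,N alphabet")
    if (ok1(object@revTir) && grepl("[^ACGTN]", object@revTir))
        msg <- c(msg, "revTir must use the A,C,G,T,N alphabet")
    if (!ok1(object@tirMismatch) || object@tirMismatch < 0L)
        msg <- c(msg, "tirMismatch must be a non-negative integer")
    if (ok1(object@fwdTir) && ok1(object@tirMismatch) &&
        object@tirMismatch >= nchar(object@fwdTir))
        msg <- c(msg, "tirMismatch must be smaller than the seed length")
    if (!ok1(object@tsdLength) || object@tsdLength < 0L)
        msg <- c(msg, "tsdLength must be a non-negative integer")
    if (!ok1(object@tsdMismatch) || object@tsdMismatch < 0L)
        msg <- c(msg, "tsdMismatch must be a non-negative integer")
    if (!ok1(object@widthMin) || !ok1(object@widthMax) ||
        object@widthMin >= object@widthMax)
        msg <- c(msg, "widthMin must be smaller than widthMax")
    if (length(msg)) msg else TRUE
})

#' Construct a TIR search query
#'
#' @param superfamily superfamily label used in element identifiers.
#' @param fwdTir forward TIR seed sequence.
#' @param revTir reverse TIR seed; default `reverseComplement(fwdTir)`.
#' @param tirMismatch Levenshtein budget for TIR matches (default 0).
#' @param tsdLength TSD length in bp; required unless `tsdMotif` is given.
#' @param tsdMotif optional fixed TSD motif.
#' @param tsdMismatch Levenshtein budget between the two TSD flanks
#'   (default 0).
#' @param widthMin,widthMax element width window in bp (defaults 300/15000;
#'   use 5000 for short-element searches with very common seeds).
#'
#' @return A [TirQuery-class] object.
#' @examples
#' TirQuery("CACTA", "CACTACAA", tsdLength = 5, tirMismatch = 1)
#' @export
TirQuery <- function(superfamily, fwdTir, revTir = NULL, tirMismatch = 0,
                     tsdLength = NULL, tsdMotif = NA_character_,
                     tsdMismatch = 0, widthMin = 300, widthMax = 15000) {
    fwdTir <- toupper(as.character(fwdTir))
    if (is.null(revTir)) revTir <- revComp(fwdTir)
    if (is.null(tsdLength)) {
        if (is.na(tsdMotif)) stop("either tsdLength or tsdMotif must be given")
        tsdLength <- nchar(tsdMotif)
    }
    new("TirQuery",
        superfamily = as.character(superfamily),
        fwdTir = fwdTir,
        revTir = toupper(as.character(revTir)),
        tirMismatch = as.integer(tirMismatch),
        tsdLength = as.integer(tsdLength),
        tsdMotif = toupper(as.character(tsdMotif)),
        tsdMismatch = as.integer(tsdMismatch),
        widthMin = as.integer(widthMin),
        widthMax = as.integer(widthMax)
    )
}

setMethod("show", "TirQuery", function(object) {
    cat("TirQuery <", object@superfamily, ">\n", sep = "")
    cat("  TIR seeds : ", object@fwdTir, " / ", object@revTir,
        "  (<= ", object@tirMismatch, " edits)\n", sep = "")
    tsd <- if (!is.na(object@tsdMotif)) {
        paste0("motif ", object@tsdMotif)
    } else {
        paste0(object@tsdLength, " nt")
    }
    cat("  TSD       : ", tsd, "  (<= ", object@tsdMismatch, " edits)\n", sep = "")
    cat("  width     : ", object@widthMin, "-", object@widthMax, " bp\n", sep = "")
})

#' Annotated set of Pack-TYPE / TIR transposable elements
#'
#' The result container of the full pipeline: element coordinates live in a
#' [GenomicRanges::GRanges] whose strand encodes orientation relative to each
#' cluster's largest member, with metadata columns \code{element_id},
#' \code{superfamily}, \code{category} (autonomous / pack / non_pack),
#' \code{cluster_id}, \code{tsd_5}, \code{tsd_3} and \code{seq}.
#'
#' @slot elements a `GRanges` of elements with the metadata columns above.
#' @slot genomeId single character naming the scanned genome/assembly.
#'
#' @export
setClass("PackTESet",
    slots = c(elements = "GRanges", genomeId = "character")
)

.packTERequiredCols <- c(
    "element_id", "superfamily", "category", "cluster_id",
    "tsd_5", "tsd_3", "seq"
)

setValidity("PackTESet", function(object) {
    msg <- character()
    mc <- S4Vectors::mcols(object@elements)
    missing <- setdiff(.packTERequiredCols, colnames(mc))
    if (length(missing))
        msg <- c(msg, paste("missing metadata columns:", paste(missing, collapse = ", ")))
    if (length(object@genomeId) != 1L)
        msg <- c(msg, "genomeId must be a single string")
    if (!length(missing)) {
        if (anyDuplicated(mc$element_id))
            msg <- c(msg, "element_id values must be unique")
        bad <- !mc$category %in% c("autonomous", "pack", "non_pack", NA_character_)
        if (any(bad)) msg <- c(msg, "category must be autonomous, pack or non_pack")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PackTESet
#'
#' @param elements `GRanges` of annotated elements.
#' @param genomeId name of the scanned genome.
#' @return A [PackTESet-class].
#' @export
PackTESet <- function(elements, genomeId = "genome") {
    new("PackTESet", elements = elements, genomeId = genomeId)
}

setMethod("show", "PackTESet", function(object) {
    gr <- object@elements
    cat("PackTESet for genome '", object@genomeId, "' with ", length(gr),
        " elements\n", sep = "")
    if (length(gr)) {
        tab <- table(S4Vectors::mcols(gr)$category, useNA = "ifany")
        cat("  categories  :",
            paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
        cat("  superfamily :",
            paste(names(table(S4Vectors::mcols(gr)$superfamily)),
                  table(S4Vectors::mcols(gr)$superfamily),
                  sep = "=", collapse = "  "), "\n")
        cat("  clusters    :",
            length(unique(S4Vectors::mcols(gr)$cluster_id)), "\n")
    }
})

#' @describeIn PackTESet-class number of annotated elements
#' @param x a `PackTESet`
#' @export
setMethod("length", "PackTESet", function(x) length(x@elements))

#' Accessors for PackTESet
#'
#' `teRanges()` returns the element coordinates as a `GRanges`;
#' `teIds()`, `teCategories()` and `teClusterIds()` return the per-element
#' identifier, functional category and cluster assignment;
#' `elementSequences()` returns the (strand-oriented) element sequences.
#'
#' @param x a [PackTESet-class]
#' @return see individual descriptions.
#' @name PackTESet-accessors
NULL

#' @rdname PackTESet-accessors
#' @export
teRanges <- function(x) x@elements

#' @rdname PackTESet-accessors
#' @export
teIds <- function(x) S4Vectors::mcols(x@elements)$element_id

#' @rdname PackTESet-accessors
#' @export
teCategories <- function(x) S4Vectors::mcols(x@elements)$category

#' @rdname PackTESet-accessors
#' @export
teClusterIds <- function(x) S4Vectors::mcols(x@elements)$cluster_id

#' @rdname PackTESet-accessors
#' @export
elementSequences <- function(x) {
    gr <- x@elements
    seqs <- Biostrings::DNAStringSet(S4Vectors::mcols(gr)$seq)
    minus <- as.character(GenomicRanges::strand(gr)) == "-"
    if (any(minus)) seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
    names(seqs) <- S4Vectors::mcols(gr)$element_id
    seqs
}

#' Simulated genome with planted ground truth
#'
#' Returned by [simulateGenome()]: the genome itself, the truth annotation of
#' planted elements and decoys, the TIR queries matching the planted seeds,
#' and the synthetic coding-sequence and transposase reference sets used to
#' seed captured fragments.
#'
#' @slot genome `DNAStringSet` of simulated contigs.
#' @slot truth `GRanges` of planted features; metadata columns include
#'   `element_id`, `family`, `superfamily`, `role` (member / singleton /
#'   n_rich / decoy), `category` (truth functional class), `orientation`,
#'   `tsd_5`, `tsd_3`.
#' @slot queries list of [TirQuery-class] matching the planted families.
#' @slot cdsDb,transposaseDb synthetic reference `DNAStringSet`s.
#' @slot config the [simulationConfig()] list used.
#'
#' @export
setClass("PackSimulation",
    slots = c(
        genome = "DNAStringSet",
        truth = "GRanges",
        queries = "list",
        cdsDb = "DNAStringSet",
        transposaseDb = "DNAStringSet",
        config = "list"
    )
)

setMethod("show", "PackSimulation", function(object) {
    roles <- table(S4Vectors::mcols(object@truth)$role)
    cat("PackSimulation: ", length(object@genome), " contig(s), ",
        sum(Biostrings::width(object@genome)), " bp (seed ",
        object@config$seed, ")\n", sep = "")
    cat("  planted :", paste(names(roles), roles, sep = "=", collapse = "  "), "\n")
    cat("  families:", length(object@config$families),
        " queries:", length(object@queries), "\n")
})

#' @rdname PackSimulation-class
#' @param x a `PackSimulation`
#' @export
simGenome <- function(x) x@genome

#' @rdname PackSimulation-class
#' @export
simTruth <- function(x) x@truth

#' @rdname PackSimulation-class
#' @export
simQueries <- function(x) x@queries
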