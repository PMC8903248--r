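#' Run the full Pack-TYPE annotation pipeline
#'
#' Orchestrates the three stages: (1) TIR/TSD candidate detection
#' ([scanGenome()]), (2) N-content filtering, greedy centroid clustering,
#' singleton removal and orientation assignment, and (3) classification of
#' each element as autonomous, pack or non_pack from similarity hits against
#' transposase and coding-sequence references, with stable identifiers minted
#' in genomic order.
#'
#' @param genome named `DNAStringSet` (or path to a FASTA file).
#' @param queries [TirQuery-class] or list of them.
#' @param cdsDb,transposaseDb reference `DNAStringSet`s (or FASTA paths);
#'   omit both to skip classification (categories become `non_pack`, as
#'   without references no hit can be found).
#' @param cdsHits,transposaseHits precomputed similarity-hit tables (12
#'   column dialect, qseqid = element id); override the corresponding
#'   database search.
#' @param backend similarity-search backend, `"internal"` or `"external"`.
#' @param genomePrefix prefix for element identifiers (e.g. `"At"`).
#' @param identityThreshold clustering identity threshold (default 0.60).
#' @param maxNFrac maximum N fraction per element (default 0.10).
#' @param cdsMinLen minimum CDS alignment length for pack classification,
#'   exceeded strictly (default 50).
#' @return A [PackTESet-class].
#' @export
packSearch <- function(genome, queries, cdsDb = NULL, transposaseDb = NULL,
                       cdsHits = NULL, transposaseHits = NULL,
                       backend = "internal", genomePrefix = "Gen",
                       identityThreshold = 0.60, maxNFrac = 0.10,
                       cdsMinLen = 50) {
    if (is.character(genome)) genome <- readGenome(genome)
    cands <- scanGenome(genome, queries)
    cands <- filterNContent(cands, maxNFrac)
    cands <- clusterElements(cands, identityThreshold)
    cands <- removeSingletons(cands)
    cands <- assignOrientation(cands)
    cands <- assignIdentifiers(cands, genomePrefix)

    if (length(cands)) {
        seqs <- elementSeqsForSearch(cands)
        if (is.null(transposaseHits) && !is.null(transposaseDb))
            transposaseHits <- runSimilaritySearch(seqs, transposaseDb,
                                                   backend = backend)
        if (is.null(cdsHits) && !is.null(cdsDb))
            cdsHits <- runSimilaritySearch(seqs, cdsDb, backend = backend)
        S4Vectors::mcols(cands)$category <- classifyElements(
            S4Vectors::mcols(cands)$element_id, transposaseHits, cdsHits,
            cdsMinLen = cdsMinLen)
    } else {
        S4Vectors::mcols(cands)$category <- character(0)
    }
    PackTESet(cands, genomeId = genomePrefix)
}

# element sequences keyed by id, plus-strand as scanned
elementSeqsForSearch <- function(cands) {
    seqs <- Biostrings::DNAStringSet(S4Vectors::mcols(cands)$seq)
    names(seqs) <- S4Vectors::mcols(cands)$element_id
    seqs
}
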