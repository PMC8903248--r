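#' Classify elements as autonomous, Pack-TYPE or non-Pack
#'
#' An element with a transposase hit of E-value below 1e-5 and alignment
#' length above 250 bp is autonomous; otherwise a coding-sequence hit with
#' E-value below 1e-5 and alignment length above `cdsMinLen` makes it a
#' Pack-TYPE element; everything else is non-Pack. Precedence is strictly
#' autonomous, then pack, then non_pack, and "length" always means alignment
#' length, not element length.
#'
#' @param elementIds character vector of element identifiers to classify.
#' @param transposaseHits,cdsHits similarity-hit tables in the 12-column
#'   tabular dialect (see [readBlastTable()]); `NULL` means no hits.
#' @param cdsMinLen minimum CDS alignment length in bp, exceeded strictly
#'   (default 50; use 250 for searches with very common short seeds).
#' @param maxEvalue hit significance cutoff (default 1e-5).
#' @return character vector of categories, parallel to `elementIds`.
#' @examples
#' hits <- data.frame(qseqid = "e1", sseqid = "tnp", pident = 95,
#'                    length = 300, mismatch = 10, gapopen = 2, qstart = 1,
#'                    qend = 300, sstart = 1, send = 300, evalue = 1e-20,
#'                    bitscore = 400)
#' classifyElements("e1", transposaseHits = hits, cdsHits = NULL)
#' @export
classifyElements <- function(elementIds, transposaseHits = NULL,
                             cdsHits = NULL, cdsMinLen = 50,
                             maxEvalue = 1e-5) {
    passing <- function(hits, minLen) {
        if (is.null(hits) || nrow(hits) == 0L) return(character(0))
        unique(hits$qseqid[hits$evalue < maxEvalue & hits$length > minLen])
    }
    auto <- passing(transposaseHits, 250)
    pack <- passing(cdsHits, cdsMinLen)
    ifelse(elementIds %in% auto, "autonomous",
           ifelse(elementIds %in% pack, "pack", "non_pack"))
}

#' Mint stable element identifiers
#'
#' Identifiers concatenate a genome prefix, the superfamily of the detecting
#' TIR query, and a numerical ID assigned in the order of discovery --
#' realised deterministically as sorted genomic order (contig, then start)
#' within each superfamily. Example: `At-CACTA-5`.
#'
#' @param cands element `GRanges` with a `superfamily` metadata column.
#' @param genomePrefix short genome label, e.g. `"At"` or `"Os"`.
#' @return `cands` with an `element_id` metadata column, re-sorted by
#'   (contig, start).
#' @export
assignIdentifiers <- function(cands, genomePrefix) {
    if (length(cands) == 0L) {
        S4Vectors::mcols(cands)$element_id <- character(0)
        return(cands)
    }
    cands <- cands[order(as.character(GenomicRanges::seqnames(cands)),
                         IRanges::start(cands))]
    fam <- S4Vectors::mcols(cands)$superfamily
    n <- stats::ave(seq_along(cands), fam, FUN = seq_along)
    ids <- paste(genomePrefix, fam, n, sep = "-")
    if (anyDuplicated(ids)) stop("duplicate element identifiers generated")
    S4Vectors::mcols(cands)$element_id <- ids
    cands
}

#' Read a tabular similarity-hit file (12-column dialect)
#'
#' Column order: qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore. Accepting precomputed hit tables decouples
#' classification from any particular search tool or version.
#'
#' @param path path to a tab-separated hit table without header.
#' @return data.frame with the standard column names.
#' @export
readBlastTable <- function(path) {
    cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")
    if (file.size(path) == 0L) {
        out <- as.data.frame(stats::setNames(
            replicate(12, logical(0), simplify = FALSE), cols))
        return(out)
    }
    hits <- utils::read.table(path, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE)
    if (ncol(hits) != 12L) stop("expected 12 tab-separated columns in ", path)
    names(hits) <- cols
    hits
}

# Karlin-Altschul parameters for the gapped +1/-1 scheme with linear gap
# cost 2. Gapped alignment admits no closed form; these are Gumbel-fit to
# the local-alignment score distribution of i.i.d. random nucleotide pairs
# under this exact scoring (lambda = pi/(sd*sqrt(6)), K from the mode). The
# ungapped closed form (lambda = log 3) would overstate significance.
.KA_LAMBDA <- 0.78
.KA_K <- 0.031

#' Run a nucleotide similarity search
#'
#' Two interchangeable backends produce hits in the same 12-column tabular
#' dialect. The `"internal"` backend is a built-in local aligner (match +1,
#' mismatch -1, gap -2 per base) whose E-values follow the Karlin-Altschul
#' formula `E = K m n exp(-lambda * S)`, with lambda and K calibrated for
#' this gapped scoring scheme on random nucleotide sequence;
#' it reports the single best local alignment per query/subject pair and
#' keeps the pipeline hermetic. The `"external"` backend shells out to the
#' standard `blastn` tool with `-max_target_seqs 500 -task blastn-short
#' -word_size 7`, applying no E-value cutoff (classification applies its
#' own).
#'
#' @param querySeqs named `DNAStringSet` (or named character) of element
#'   sequences.
#' @param db named `DNAStringSet` (or path to a FASTA) of reference
#'   sequences, e.g. coding sequences or transposases.
#' @param backend `"internal"` or `"external"`.
#' @param maxEvalue report only hits at or below this E-value (default 10,
#'   mirroring the default report threshold of common search tools).
#' @return data.frame of hits in 12-column tabular form.
#' @export
runSimilaritySearch <- function(querySeqs, db,
                                backend = c("internal", "external"),
                                maxEvalue = 10) {
    backend <- match.arg(backend)
    if (is.character(querySeqs)) querySeqs <- Biostrings::DNAStringSet(querySeqs)
    if (is.character(db) && length(db) == 1L && file.exists(db))
        db <- Biostrings::readDNAStringSet(db)
    if (is.character(db)) db <- Biostrings::DNAStringSet(db)
    if (is.null(names(querySeqs))) names(querySeqs) <- paste0("q", seq_along(querySeqs))
    if (length(db) && is.null(names(db))) names(db) <- paste0("s", seq_along(db))
    emptyHits <- function() readBlastTableEmpty()
    if (length(db) == 0L || length(querySeqs) == 0L) return(emptyHits())
    if (backend == "internal") {
        .internalSearch(querySeqs, db, maxEvalue)
    } else {
        .externalSearch(querySeqs, db, maxEvalue)
    }
}

readBlastTableEmpty <- function() {
    data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
               length = integer(), mismatch = integer(), gapopen = integer(),
               qstart = integer(), qend = integer(), sstart = integer(),
               send = integer(), evalue = numeric(), bitscore = numeric(),
               stringsAsFactors = FALSE)
}

.internalSearch <- function(querySeqs, db, maxEvalue) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE)
    nDb <- sum(Biostrings::width(db))
    rows <- list()
    rcQuery <- Biostrings::reverseComplement(querySeqs)
    for (si in seq_along(db)) {
        # both query strands, as any nucleotide search tool would
        alnP <- Biostrings::pairwiseAlignment(
            querySeqs, db[[si]], type = "local",
            substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
        alnM <- Biostrings::pairwiseAlignment(
            rcQuery, db[[si]], type = "local",
            substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
        useM <- Biostrings::score(alnM) > Biostrings::score(alnP)
        fld <- function(f, ...) ifelse(useM, f(alnM, ...), f(alnP, ...))
        sc <- fld(Biostrings::score)
        alnLen <- fld(Biostrings::nchar)
        ev <- .KA_K * Biostrings::width(querySeqs) * nDb * exp(-.KA_LAMBDA * sc)
        keep <- which(sc > 0 & ev <= maxEvalue)
        if (!length(keep)) next
        gapOpens <- function(a) {
            ind <- Biostrings::nindel(a)
            as.integer(ind@insertion[, "Length"] + ind@deletion[, "Length"])
        }
        nGapOpen <- ifelse(useM, gapOpens(alnM), gapOpens(alnP))[keep]
        qs <- fld(function(a) IRanges::start(Biostrings::pattern(a)))
        qe <- fld(function(a) IRanges::end(Biostrings::pattern(a)))
        qlen <- Biostrings::width(querySeqs)
        # minus-strand coordinates reported on the original query, reversed
        qstart <- ifelse(useM, qlen - qe + 1L, qs)
        qend <- ifelse(useM, qlen - qs + 1L, qe)
        ss <- fld(function(a) IRanges::start(Biostrings::subject(a)))
        se <- fld(function(a) IRanges::end(Biostrings::subject(a)))
        sstart <- ifelse(useM, se, ss) # sstart > send flags the minus strand
        send <- ifelse(useM, ss, se)
        rows[[length(rows) + 1L]] <- data.frame(
            qseqid = names(querySeqs)[keep],
            sseqid = names(db)[si],
            pident = 100 * fld(Biostrings::nmatch)[keep] / alnLen[keep],
            length = alnLen[keep],
            mismatch = fld(Biostrings::nmismatch)[keep],
            gapopen = nGapOpen,
            qstart = qstart[keep],
            qend = qend[keep],
            sstart = sstart[keep],
            send = send[keep],
            evalue = ev[keep],
            bitscore = (.KA_LAMBDA * sc[keep] - log(.KA_K)) / log(2),
            stringsAsFactors = FALSE)
    }
    if (!length(rows)) return(readBlastTableEmpty())
    out <- do.call(rbind, rows)
    out[order(out$qseqid, out$evalue), , drop = FALSE]
}

.externalSearch <- function(querySeqs, db, maxEvalue) {
    blastn <- Sys.which("blastn")
    makedb <- Sys.which("makeblastdb")
    if (blastn == "" || makedb == "")
        stop("external search backend not found on PATH; use backend = ",
             "\"internal\" or supply a precomputed hit table")
    td <- tempfile("blast")
    dir.create(td)
    on.exit(unlink(td, recursive = TRUE), add = TRUE)
    qfa <- file.path(td, "query.fa")
    dfa <- file.path(td, "db.fa")
    outTab <- file.path(td, "hits.tsv")
    Biostrings::writeXStringSet(querySeqs, qfa)
    Biostrings::writeXStringSet(db, dfa)
    system2(makedb, c("-in", dfa, "-dbtype", "nucl"),
            stdout = FALSE, stderr = FALSE)
    system2(blastn, c("-query", qfa, "-db", dfa, "-max_target_seqs", "500",
                      "-task", "blastn-short", "-word_size", "7",
                      "-evalue", format(maxEvalue), "-outfmt", "6",
                      "-out", outTab),
            stdout = FALSE, stderr = FALSE)
    if (!file.exists(outTab) || file.size(outTab) == 0L)
        return(readBlastTableEmpty())
    readBlastTable(outTab)
}
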