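#' Read a genome from a FASTA file
#'
#' Sequences are uppercased and any IUPAC ambiguity code other than N is
#' masked to N (with a warning); reference assemblies routinely contain such
#' codes and the pipeline already filters elements on N content downstream.
#'
#' @param path path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], one entry per contig.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtn"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    x <- Biostrings::readDNAStringSet(path)
    if (length(x) == 0L) stop("no sequences found in ", path)
    # FASTA headers: contig id is the first whitespace-delimited token
    names(x) <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(names(x)))
        stop("duplicate contig ids in ", path, ": ",
             paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
    af <- Biostrings::alphabetFrequency(x)
    ambig <- setdiff(colnames(af), c("A", "C", "G", "T", "N", "-", "+", "."))
    nAmbig <- sum(af[, ambig, drop = FALSE])
    if (nAmbig > 0) {
        warning(nAmbig, " ambiguity base(s) masked to N")
        x <- Biostrings::replaceAmbiguities(x, new = "N")
    }
    x
}

#' Reverse complement of a nucleotide string
#'
#' Vectorised over its input; N is its own complement and the operation is an
#' involution.
#'
#' @param seq character vector over the A,C,G,T,N alphabet (case-insensitive).
#' @return character vector of reverse complements.
#' @examples
#' revComp("CACTACAA")
#' @export
revComp <- function(seq) {
    seq <- toupper(seq)
    bad <- grepl("[^ACGTN]", seq)
    if (any(bad)) stop("sequence contains characters outside A,C,G,T,N")
    out <- character(length(seq))
    nz <- nchar(seq) > 0L
    out[nz] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(seq[nz]))
    )
    out
}

#' Write pipeline annotations to GFF3, TSV and FASTA
#'
#' Emits three files sharing a prefix: `<prefix>.gff3` with one feature per
#' element (attributes ID, superfamily, category, cluster, TSD sequences),
#' `<prefix>.tsv` mirroring all fields, and `<prefix>.fasta` with the element
#' sequences oriented according to their strand. All coordinates are 1-based
#' inclusive.
#'
#' @param records a `GRanges` of elements (as produced by the pipeline, with
#'   metadata columns `element_id`, `superfamily`, `category`, `cluster_id`,
#'   `tsd_5`, `tsd_3`) or a [PackTESet-class].
#' @param genome the genome `DNAStringSet` the records refer to.
#' @param outPrefix output path prefix.
#' @return Invisibly, the vector of files written.
#' @export
writeAnnotations <- function(records, genome, outPrefix) {
    if (is(records, "PackTESet")) records <- teRanges(records)
    stopifnot(is(records, "GRanges"))
    files <- paste0(outPrefix, c(".gff3", ".tsv", ".fasta"))

    if (length(records)) {
        contigs <- as.character(GenomicRanges::seqnames(records))
        unknown <- setdiff(contigs, names(genome))
        if (length(unknown))
            stop("records refer to unknown contigs: ",
                 paste(unique(unknown), collapse = ", "))
        lens <- Biostrings::width(genome)[match(contigs, names(genome))]
        if (any(IRanges::start(records) < 1L) || any(IRanges::end(records) > lens))
            stop("record out of contig bounds")
    }

    if (length(records) == 0L) {
        writeLines("##gff-version 3", files[1])
        writeLines(paste(c("contig", "start", "end", "strand", "element_id",
                           "superfamily", "category", "cluster_id",
                           "tsd_seq_5", "tsd_seq_3", "width"),
                         collapse = "\t"), files[2])
        Biostrings::writeXStringSet(Biostrings::DNAStringSet(), files[3])
        return(invisible(files))
    }

    mc <- S4Vectors::mcols(records)
    gff <- GenomicRanges::granges(records)
    S4Vectors::mcols(gff) <- S4Vectors::DataFrame(
        source = rep("packScan", length(records)),
        type = rep("terminal_inverted_repeat_element", length(records)),
        ID = mc$element_id,
        superfamily = mc$superfamily,
        category = mc$category,
        cluster = as.character(mc$cluster_id),
        tsd_5 = mc$tsd_5,
        tsd_3 = mc$tsd_3
    )
    rtracklayer::export(gff, files[1], format = "gff3")

    tab <- data.frame(
        contig = as.character(GenomicRanges::seqnames(records)),
        start = IRanges::start(records),
        end = IRanges::end(records),
        strand = as.character(GenomicRanges::strand(records)),
        element_id = mc$element_id,
        superfamily = mc$superfamily,
        category = mc$category,
        cluster_id = mc$cluster_id,
        tsd_seq_5 = mc$tsd_5,
        tsd_seq_3 = mc$tsd_3,
        width = IRanges::width(records),
        stringsAsFactors = FALSE
    )
    utils::write.table(tab, files[2], sep = "\t", quote = FALSE,
                       row.names = FALSE)

    seqs <- extractElementSeqs(records, genome)
    Biostrings::writeXStringSet(seqs, files[3])
    invisible(files)
}

#' Extract (strand-oriented) element sequences from a genome
#'
#' Minus-strand elements are returned reverse-complemented.
#'
#' @param records `GRanges` of elements.
#' @param genome `DNAStringSet`.
#' @return A `DNAStringSet` named by `element_id` when present.
#' @export
extractElementSeqs <- function(records, genome) {
    if (length(records) == 0L) return(Biostrings::DNAStringSet())
    contigs <- as.character(GenomicRanges::seqnames(records))
    seqs <- Biostrings::DNAStringSet(vapply(seq_along(records), function(i) {
        as.character(Biostrings::subseq(genome[[contigs[i]]],
                                        IRanges::start(records)[i],
                                        IRanges::end(records)[i]))
    }, character(1)))
    minus <- as.character(GenomicRanges::strand(records)) == "-"
    if (any(minus)) seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
    ids <- S4Vectors::mcols(records)$element_id
    if (!is.null(ids)) names(seqs) <- ids
    seqs
}
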