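#' Read a TIR query table
#'
#' Tab- or comma-separated table with a header; columns `superfamily`,
#' `fwd_tir` and optionally `rev_tir`, `tir_mismatch`, `tsd_length`,
#' `tsd_motif`, `tsd_mismatch`, `width_min`, `width_max`. Missing optional
#' columns fall back to the [TirQuery()] defaults (reverse seed =
#' reverse complement, width window 300--15000 bp, zero budgets).
#'
#' @param path path to the query table.
#' @return list of [TirQuery-class] objects, in file order.
#' @export
readTirQueries <- function(path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, sep = sep, header = TRUE,
                             stringsAsFactors = FALSE)
    need <- c("superfamily", "fwd_tir")
    if (!all(need %in% names(tab)))
        stop("query table needs at least columns: ",
             paste(need, collapse = ", "))
    getCol <- function(col, default, i) {
        if (!col %in% names(tab)) return(default)
        v <- tab[[col]][i]
        if (is.na(v) || identical(v, "")) default else v
    }
    lapply(seq_len(nrow(tab)), function(i) {
        motif <- getCol("tsd_motif", NA_character_, i)
        tsdLen <- getCol("tsd_length", NULL, i)
        if (is.null(tsdLen) && is.na(motif))
            stop("row ", i, ": give tsd_length or tsd_motif")
        TirQuery(
            superfamily = tab$superfamily[i],
            fwdTir = tab$fwd_tir[i],
            revTir = if ("rev_tir" %in% names(tab) &&
                         !is.na(tab$rev_tir[i]) && nzchar(tab$rev_tir[i]))
                tab$rev_tir[i] else NULL,
            tirMismatch = getCol("tir_mismatch", 0, i),
            tsdLength = tsdLen,
            tsdMotif = motif,
            tsdMismatch = getCol("tsd_mismatch", 0, i),
            widthMin = getCol("width_min", 300, i),
            widthMax = getCol("width_max", 15000, i)
        )
    })
}
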