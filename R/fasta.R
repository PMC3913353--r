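# Sequence records, taxon groups and FASTA / taxonomy-table I/O.
#
# A sequence record set is a plain data.frame with columns
#   id, sequence, kingdom, taxon, reoriented
# which keeps the curation pipeline transparent and easy to audit.

.normalize_sequence <- function(x) {
    x <- toupper(x)
    x <- chartr("U.", "T-", x)
    x
}

.validate_records <- function(records) {
    stopifnot(is.data.frame(records))
    need <- c("id", "sequence")
    miss <- setdiff(need, names(records))
    if (length(miss) > 0L)
        stop("records missing column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
    if (anyDuplicated(records$id))
        stop("duplicate sequence id(s): ",
             paste(unique(records$id[duplicated(records$id)]), collapse = ", "),
             call. = FALSE)
    if (any(!nzchar(records$sequence)))
        stop("empty sequence(s)", call. = FALSE)
    invisible(records)
}

.as_record_df <- function(id, sequence, kingdom = NA_character_,
                          taxon = NA_character_, reoriented = FALSE) {
    data.frame(id = as.character(id), sequence = as.character(sequence),
               kingdom = kingdom, taxon = taxon,
               reoriented = reoriented, stringsAsFactors = FALSE)
}

#' Read a taxonomy table
#'
#' A tab-separated file with a header whose first column is `id`, followed
#' by `kingdom` and one or more rank columns (at least `taxon`, or named
#' ranks such as `genus`, `family`).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with one row per sequence id.
#' @export
read_taxonomy <- function(path) {
    tax <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(c("id", "kingdom") %in% names(tax)))
        stop("taxonomy table must have 'id' and 'kingdom' columns",
             call. = FALSE)
    if (anyDuplicated(tax$id))
        stop("duplicate id(s) in taxonomy table", call. = FALSE)
    bad <- setdiff(unique(tax$kingdom), c("prokaryote", "fungi"))
    if (length(bad) > 0L)
        stop("unknown kingdom(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    tax
}

#' Read sequences from FASTA, optionally joined with a taxonomy table
#'
#' Sequences are uppercased, RNA `U` is mapped to `T` and `.` gaps to `-`.
#' Record ids are the first whitespace-delimited token of each header.
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @param taxonomy Optional taxonomy: a path to a TSV (see
#'   [read_taxonomy()]) or an already-read data.frame.
#' @param rank Which taxonomy column provides the grouping taxon
#'   (default `"taxon"`; falls back to the given rank name, e.g. `"genus"`).
#' @param require_taxonomy If `TRUE`, every FASTA id must appear in the
#'   taxonomy table.
#' @return A record data.frame (columns id, sequence, kingdom, taxon,
#'   reoriented).
#' @export
read_fasta <- function(path, taxonomy = NULL, rank = "taxon",
                       require_taxonomy = !is.null(taxonomy)) {
    ss <- Biostrings::readBStringSet(path)
    ids <- vapply(strsplit(names(ss), "[ \t]"), `[[`, character(1), 1L)
    seqs <- .normalize_sequence(as.character(ss))
    for (i in seq_along(seqs))
        .check_iupac(setdiff(strsplit(seqs[i], "")[[1]], "-"),
                     context = paste0("sequence '", ids[i], "'"))
    rec <- .as_record_df(ids, seqs)
    if (!is.null(taxonomy)) {
        tax <- if (is.character(taxonomy)) read_taxonomy(taxonomy) else taxonomy
        col <- if (rank %in% names(tax)) rank else "taxon"
        if (!col %in% names(tax))
            stop("taxonomy table has no '", rank, "' or 'taxon' column",
                 call. = FALSE)
        m <- match(rec$id, tax$id)
        if (require_taxonomy && anyNA(m))
            stop("id(s) absent from taxonomy table: ",
                 paste(rec$id[is.na(m)], collapse = ", "), call. = FALSE)
        rec$kingdom <- tax$kingdom[m]
        rec$taxon <- tax[[col]][m]
    }
    .validate_records(rec)
}

#' Write sequence records (or a named character vector) to FASTA
#'
#' @param records A record data.frame or a named character vector of
#'   sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
    if (is.data.frame(records)) {
        .validate_records(records)
        seqs <- structure(records$sequence, names = records$id)
    } else {
        stopifnot(is.character(records), !is.null(names(records)))
        seqs <- records
    }
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                                width = width)
    invisible(path)
}

#' Construct a taxon group
#'
#' The unit of probe design: an ordered set of sequence records sharing one
#' taxon (and kingdom).
#'
#' @param taxon Group label (e.g. a genus name).
#' @param members Record data.frame; all rows must carry `taxon` (or have
#'   it `NA`, in which case it is filled in) and agree on the kingdom.
#' @return An object of class `taxon_group`.
#' @export
taxon_group <- function(taxon, members) {
    .validate_records(members)
    if (is.null(members$taxon)) members$taxon <- NA_character_
    members$taxon[is.na(members$taxon)] <- taxon
    if (!all(members$taxon == taxon))
        stop("all members must share taxon '", taxon, "'", call. = FALSE)
    kd <- unique(members$kingdom[!is.na(members$kingdom)])
    if (length(kd) > 1L)
        stop("members of '", taxon, "' span multiple kingdoms", call. = FALSE)
    structure(list(taxon = taxon,
                   kingdom = if (length(kd)) kd else NA_character_,
                   members = members),
              class = "taxon_group")
}

#' @export
print.taxon_group <- function(x, ...) {
    cat(sprintf("<taxon_group> %s (%s): %d sequence(s), lengths %d-%d\n",
                x$taxon, x$kingdom, nrow(x$members),
                min(nchar(x$members$sequence)),
                max(nchar(x$members$sequence))))
    invisible(x)
}

#' @export
length.taxon_group <- function(x) nrow(x$members)
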