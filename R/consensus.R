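# IUPAC degenerate consensus construction and sliding-window probe
# enumeration -- the heart of the design strategy.

#' Probe design parameters
#'
#' @param probe_length Probe length l in bases (default 25).
#' @param max_degeneracy Maximum degeneracy of a degenerate probe
#'   (default 2000).
#' @param specificity_threshold Minimum probe/non-target similarity that
#'   counts as a cross-hybridization, in (0, 1] (default 0.88; inclusive).
#' @param max_cross_hyb Maximum tolerated number of non-target
#'   cross-hybridizations per degenerate probe (default 100).
#' @param job_count Number of parallel screening jobs N (default 1).
#' @return A `design_parameters` list.
#' @export
design_parameters <- function(probe_length = 25L, max_degeneracy = 2000,
                              specificity_threshold = 0.88,
                              max_cross_hyb = 100L, job_count = 1L) {
    stopifnot(probe_length >= 1, max_degeneracy >= 1,
              specificity_threshold > 0, specificity_threshold <= 1,
              max_cross_hyb >= 0, job_count >= 1)
    structure(list(probe_length = as.integer(probe_length),
                   max_degeneracy = max_degeneracy,
                   specificity_threshold = specificity_threshold,
                   max_cross_hyb = as.integer(max_cross_hyb),
                   job_count = as.integer(job_count)),
              class = "design_parameters")
}

#' Build the IUPAC consensus of a group alignment
#'
#' Column rule: with m rows, let U be the number of unknown characters in
#' the column.  If U < m/2 (strictly), the consensus symbol is the IUPAC
#' code for the set of specific bases observed in the column, and every
#' unknown character of that column is replaced by this code in the
#' corrected alignment (improving the alignment and repairing likely
#' sequencing errors); otherwise the consensus gets a gap and the column
#' is left untouched.
#'
#' @param aln A `dna_alignment`.
#' @param taxon Group label carried on the consensus.
#' @param unknown Which characters count as unknown: `"non_acgt"`
#'   (default: gaps, N and every other ambiguity code) or `"strict"`
#'   (only N and gaps, with other ambiguity codes contributing their base
#'   sets to the consensus code).
#' @return List with `consensus` (class `consensus_sequence`: `taxon`,
#'   `text`, `columns`) and `alignment` (the corrected `dna_alignment`).
#' @export
build_consensus <- function(aln, taxon = NA_character_,
                            unknown = c("non_acgt", "strict")) {
    stopifnot(inherits(aln, "dna_alignment"))
    unknown <- match.arg(unknown)
    M <- .aln_chars(aln)
    m <- nrow(M)
    unk <- if (unknown == "non_acgt")
        !(M %in% c("A", "C", "G", "T")) else M %in% c("N", "-")
    dim(unk) <- dim(M)
    map <- .iupac_map()
    text <- character(ncol(M))
    for (cc in seq_len(ncol(M))) {
        U <- sum(unk[, cc])
        if (U >= m / 2) {
            text[cc] <- "-"
            next
        }
        known <- M[!unk[, cc], cc]
        bases <- unique(unlist(strsplit(unname(map[unique(known)]), "")))
        code <- code_for_set(bases)
        text[cc] <- code
        if (U > 0L) M[unk[, cc], cc] <- code
    }
    corrected <- new_alignment(
        aln$ids, apply(M, 1L, paste, collapse = ""))
    consensus <- structure(list(taxon = taxon,
                                text = paste(text, collapse = ""),
                                columns = ncol(M)),
                           class = "consensus_sequence")
    list(consensus = consensus, alignment = corrected)
}

#' @export
print.consensus_sequence <- function(x, ...) {
    cat(sprintf("<consensus_sequence> %s: %d column(s), %d gap(s)\n",
                x$taxon, x$columns,
                sum(strsplit(x$text, "")[[1]] == "-")))
    invisible(x)
}

#' Enumerate candidate degenerate probes along a consensus
#'
#' A window of length l slides over the consensus; every gap-free window
#' whose degeneracy does not exceed the maximum becomes a candidate probe.
#' Start positions are 1-based on the consensus with gap columns counted,
#' so positions are stable identifiers.  Each probe's weight (used for
#' load balancing) equals its degeneracy.
#'
#' @param consensus A `consensus_sequence` (or plain IUPAC/gap string).
#' @param params A [design_parameters()] object.
#' @return Data.frame: taxon, start, sequence, degeneracy, weight;
#'   sorted by start.
#' @export
enumerate_probes <- function(consensus, params = design_parameters()) {
    text <- if (inherits(consensus, "consensus_sequence"))
        consensus$text else consensus
    taxon <- if (inherits(consensus, "consensus_sequence"))
        consensus$taxon else NA_character_
    l <- params$probe_length
    C <- nchar(text)
    if (l > C) stop("probe length exceeds consensus length", call. = FALSE)
    chars <- strsplit(text, "")[[1]]
    sizes <- ifelse(chars == "-", NA_real_,
                    .iupac$size[match(chars, names(.iupac_map()))])
    starts <- seq_len(C - l + 1L)
    keep <- logical(length(starts))
    deg <- numeric(length(starts))
    for (p in starts) {
        s <- sizes[p:(p + l - 1L)]
        if (anyNA(s)) next
        d <- prod(s)
        if (d <= params$max_degeneracy) {
            keep[p] <- TRUE
            deg[p] <- d
        }
    }
    data.frame(taxon = taxon, start = starts[keep],
               sequence = substring(text, starts[keep],
                                    starts[keep] + l - 1L),
               degeneracy = deg[keep], weight = deg[keep],
               stringsAsFactors = FALSE)
}

#' Classify probe expansions as known or explorative
#'
#' An expansion of a degenerate probe is *known* when it occurs as an
#' exact forward-strand substring of at least one group member; otherwise
#' it is *explorative* -- it targets combinations of observed variation not
#' yet seen in any database sequence, and may detect undiscovered
#' relatives of the group.
#'
#' @param probe One-row probe data.frame (from [enumerate_probes()]) or a
#'   plain IUPAC string.
#' @param group The `taxon_group` the probe was designed for.
#' @param cap Expansion safety cap (default: the probe's degeneracy).
#' @return List with character vectors `known` and `explorative`; together
#'   they are exactly the expansion set.
#' @export
classify_expansions <- function(probe, group, cap = NULL) {
    seqd <- if (is.data.frame(probe)) probe$sequence[1L] else probe
    if (is.null(cap)) cap <- degeneracy_of(seqd)
    ex <- iupac_expand(seqd, cap = cap)
    seqs <- .group_seqs(group)
    known <- vapply(ex, function(e) any(grepl(e, seqs, fixed = TRUE)),
                    logical(1), USE.NAMES = FALSE)
    list(known = ex[known], explorative = ex[!known])
}

#' Write / read a probe candidate table
#'
#' @param probes Probe data.frame.
#' @param path TSV path.
#' @export
write_probes <- function(probes, path) {
    write.table(probes, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname write_probes
#' @export
read_probes <- function(path) {
    read.delim(path, stringsAsFactors = FALSE)
}
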