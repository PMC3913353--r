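# Curated group database construction: quality filtering, orientation
# correction against a trusted reference, dereplication at 100% identity,
# and homogeneity screening of each taxon group.

#' Curation criteria
#'
#' Quality rules applied to each SSU rRNA sequence before grouping:
#' length strictly above `min_length` and strictly below the
#' kingdom-specific maximum; a taxon assignment when `require_taxon`;
#' a fraction of unknown characters (anything outside A/C/G/T) strictly
#' below `max_unknown_fraction`; and no run of unknown characters longer
#' than `max_unknown_run`.
#'
#' @param min_length Minimum length, exclusive (default 1200).
#' @param max_length_prokaryote Maximum length for prokaryotes, exclusive
#'   (default 1600, the 16S gene scale).
#' @param max_length_fungi Maximum length for fungi, exclusive
#'   (default 1800, the 18S gene scale).
#' @param max_unknown_fraction Maximum unknown-character fraction,
#'   exclusive (default 0.01).
#' @param max_unknown_run Longest tolerated run of consecutive unknown
#'   characters, inclusive (default 5).
#' @param require_taxon Reject records without a taxon label?
#' @return A `curation_criteria` list.
#' @export
curation_criteria <- function(min_length = 1200L,
                              max_length_prokaryote = 1600L,
                              max_length_fungi = 1800L,
                              max_unknown_fraction = 0.01,
                              max_unknown_run = 5L,
                              require_taxon = TRUE) {
    stopifnot(min_length < max_length_prokaryote,
              min_length < max_length_fungi,
              max_unknown_fraction > 0, max_unknown_run >= 0)
    structure(list(min_length = min_length,
                   max_length_prokaryote = max_length_prokaryote,
                   max_length_fungi = max_length_fungi,
                   max_unknown_fraction = max_unknown_fraction,
                   max_unknown_run = max_unknown_run,
                   require_taxon = require_taxon),
              class = "curation_criteria")
}

.dispositions <- c("kept", "rejected_length", "rejected_taxon",
                   "rejected_unknown_fraction", "rejected_unknown_run",
                   "removed_duplicate", "removed_inhomogeneous")

#' Quality-filter a single sequence record
#'
#' Rules are tested in a fixed order (length, taxon, unknown fraction,
#' unknown run) and the first failure is reported.
#'
#' @param rec One-row record data.frame.
#' @param criteria A [curation_criteria()] object.
#' @return One of `"kept"`, `"rejected_length"`, `"rejected_taxon"`,
#'   `"rejected_unknown_fraction"`, `"rejected_unknown_run"`.
#' @export
filter_sequence <- function(rec, criteria = curation_criteria()) {
    stopifnot(is.data.frame(rec), nrow(rec) == 1L)
    len <- nchar(rec$sequence)
    maxlen <- switch(rec$kingdom,
                     prokaryote = criteria$max_length_prokaryote,
                     fungi = criteria$max_length_fungi,
                     stop("unknown kingdom: ", rec$kingdom, call. = FALSE))
    if (!(len > criteria$min_length && len < maxlen))
        return("rejected_length")
    if (criteria$require_taxon &&
        (is.na(rec$taxon) || !nzchar(rec$taxon)))
        return("rejected_taxon")
    unknown <- !strsplit(rec$sequence, "")[[1]] %in% c("A", "C", "G", "T")
    if (sum(unknown) / len >= criteria$max_unknown_fraction)
        return("rejected_unknown_fraction")
    if (any(unknown)) {
        r <- rle(unknown)
        if (max(r$lengths[r$values]) > criteria$max_unknown_run)
            return("rejected_unknown_run")
    }
    "kept"
}

#' Correct the strand orientation of a record
#'
#' The record and its reverse complement are each locally aligned against a
#' trusted same-kingdom reference; if the reverse complement scores
#' strictly higher, the record is flipped and flagged `reoriented`.
#'
#' @param rec One-row record data.frame.
#' @param reference A reference sequence: a one-row record data.frame or a
#'   plain string.
#' @param scoring Alignment scoring parameters.
#' @return The (possibly flipped) record.
#' @export
orient_sequence <- function(rec, reference, scoring = .default_scoring) {
    ref <- if (is.data.frame(reference)) reference$sequence[1L] else reference
    if (is.na(ref) || !nzchar(ref)) stop("empty reference", call. = FALSE)
    fwd <- pairwise_align(rec$sequence, ref, "local", scoring)$score
    rev <- pairwise_align(reverse_complement(rec$sequence), ref, "local",
                          scoring)$score
    if (fwd >= rev) return(rec)
    rec$sequence <- reverse_complement(rec$sequence)
    rec$reoriented <- TRUE
    rec
}

#' Remove redundant sequences from a group
#'
#' Implements single-linkage dereplication at 100% identity with coverage
#' required on only one sequence of a pair: a member is removed when it is
#' identical to, or an exact substring of, another member.  Among exact
#' duplicates the longer sequence survives; ties go to the earlier input.
#'
#' @param group A `taxon_group`.
#' @return The dereplicated `taxon_group`, with the removed ids in
#'   attribute `"removed_ids"`.
#' @export
dereplicate_group <- function(group) {
    stopifnot(inherits(group, "taxon_group"), length(group) >= 1L)
    m <- group$members
    ord <- order(-nchar(m$sequence), method = "radix")      # stable: ties keep input order
    keep_seq <- character(0)
    keep_idx <- integer(0)
    removed <- integer(0)
    for (i in ord) {
        s <- m$sequence[i]
        if (length(keep_seq) > 0L &&
            any(vapply(keep_seq, function(k) grepl(s, k, fixed = TRUE),
                       logical(1))))
            removed <- c(removed, i)
        else {
            keep_seq <- c(keep_seq, s)
            keep_idx <- c(keep_idx, i)
        }
    }
    out <- taxon_group(group$taxon, m[sort(keep_idx), , drop = FALSE])
    attr(out, "removed_ids") <- m$id[sort(removed)]
    out
}

#' Remove inhomogeneous (likely misannotated) sequences from a group
#'
#' The group is aligned, each sequence embedded as its row of the pairwise
#' distance matrix, and K-means (K = 2, deterministic farthest-pair
#' initialization, Lloyd iterations) splits the embedding.  The largest
#' cluster is retained -- unless the two cluster centroids are separated by
#' less than `margin` (RMS per-coordinate distance, i.e. on the
#' sequence-distance scale), in which case the group is considered
#' homogeneous and kept whole.  At most half the group is ever removed;
#' a size tie keeps the cluster containing the earlier input sequence.
#'
#' @param group A `taxon_group`.
#' @param margin Homogeneity margin on the distance scale (default 0.10).
#' @param scoring Alignment scoring parameters.
#' @return The screened `taxon_group`, removed ids in attribute
#'   `"removed_ids"`.
#' @export
homogeneity_filter <- function(group, margin = 0.10,
                               scoring = .default_scoring) {
    stopifnot(inherits(group, "taxon_group"))
    n <- length(group)
    pass <- function() {
        attr(group, "removed_ids") <- character(0)
        group
    }
    if (n < 2L) return(pass())
    aln <- progressive_align(group, scoring)
    D <- distance_matrix(aln)
    if (max(D) == 0) return(pass())
    # farthest pair initializes the two centers (first maximal pair in
    # column-major order: deterministic)
    w <- which.max(D)
    i0 <- (w - 1L) %% n + 1L
    j0 <- (w - 1L) %/% n + 1L
    km <- suppressWarnings(
        kmeans(D, centers = D[c(i0, j0), , drop = FALSE],
               iter.max = 100L, algorithm = "Lloyd"))
    sizes <- tabulate(km$cluster, 2L)
    if (any(sizes == 0L)) return(pass())
    sep <- sqrt(mean((km$centers[1L, ] - km$centers[2L, ])^2))
    if (sep < margin) return(pass())
    big <- if (sizes[1L] != sizes[2L]) which.max(sizes) else
        km$cluster[1L]                 # tie: cluster of the earliest input
    keep <- km$cluster == big
    out <- taxon_group(group$taxon,
                       group$members[keep, , drop = FALSE])
    attr(out, "removed_ids") <- group$members$id[!keep]
    out
}

#' Build the curated group database
#'
#' Applies the full curation pipeline in order: per-sequence quality
#' filter, grouping at the chosen rank, orientation correction against the
#' reference, dereplication, and homogeneity screening.  Every input
#' record receives exactly one disposition in the report.
#'
#' @param records Record data.frame (with kingdom and taxon columns
#'   filled, e.g. from [read_fasta()] with a taxonomy table).
#' @param reference Reference sequence for orientation (record row or
#'   string).
#' @param criteria A [curation_criteria()] object.
#' @param margin Homogeneity margin, see [homogeneity_filter()].
#' @param scoring Alignment scoring parameters.
#' @return List with `groups` (named list of `taxon_group`) and `report`
#'   (data.frame: id, taxon, disposition, reoriented), of class
#'   `curation_result`.
#' @export
build_database <- function(records, reference,
                           criteria = curation_criteria(),
                           margin = 0.10, scoring = .default_scoring) {
    .validate_records(records)
    if (nrow(records) == 0L) stop("empty input", call. = FALSE)
    disposition <- vapply(seq_len(nrow(records)), function(i)
        filter_sequence(records[i, , drop = FALSE], criteria), character(1))
    records$reoriented <- FALSE

    kept <- which(disposition == "kept")
    groups <- list()
    for (tx in unique(records$taxon[kept][!is.na(records$taxon[kept])])) {
        ix <- kept[!is.na(records$taxon[kept]) & records$taxon[kept] == tx]
        g <- records[ix, , drop = FALSE]
        for (k in seq_len(nrow(g)))
            g[k, ] <- orient_sequence(g[k, , drop = FALSE], reference,
                                      scoring)
        records$sequence[ix] <- g$sequence
        records$reoriented[ix] <- g$reoriented

        grp <- dereplicate_group(taxon_group(tx, g))
        disposition[match(attr(grp, "removed_ids"), records$id)] <-
            "removed_duplicate"
        grp <- homogeneity_filter(grp, margin, scoring)
        disposition[match(attr(grp, "removed_ids"), records$id)] <-
            "removed_inhomogeneous"
        if (length(grp) > 0L) groups[[tx]] <- grp
    }
    report <- data.frame(id = records$id, taxon = records$taxon,
                         disposition = disposition,
                         reoriented = records$reoriented,
                         stringsAsFactors = FALSE)
    structure(list(groups = groups, report = report),
              class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
    cat(sprintf("<curation_result> %d group(s) from %d record(s)\n",
                length(x$groups), nrow(x$report)))
    print(table(factor(x$report$disposition, levels = .dispositions)))
    invisible(x)
}

#' Per-group disposition counts from a curation report
#'
#' @param result A `curation_result`.
#' @return Data.frame of counts per taxon and disposition; counts sum to
#'   the input size within each taxon.
#' @export
curation_counts <- function(result) {
    stopifnot(inherits(result, "curation_result"))
    as.data.frame(table(taxon = result$report$taxon,
                        disposition = factor(result$report$disposition,
                                             levels = .dispositions)),
                  responseName = "count", stringsAsFactors = FALSE)
}
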