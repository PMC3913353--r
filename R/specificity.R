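# Cross-hybridization screening of probe expansions against the reference
# group database.  The search is an exhaustive seed-and-extend scan:
# every ungapped window of every database sequence (both strands) whose
# similarity to the probe reaches the specificity threshold is reported.
# The seed width is chosen so that the pigeonhole guarantee holds (a hit
# with at most k mismatches always contains one exact seed), making the
# scan equivalent to a brute-force all-window Hamming comparison.

.allowed_mismatches <- function(l, threshold) {
    floor(l * (1 - threshold) + 1e-9)
}

.seed_width <- function(l, k) {
    max(1L, min(7L, l %/% (k + 1L)))
}

#' Ungapped probe/window similarity
#'
#' @param probe,window Equal-length ACGT strings.
#' @return Fraction of identical positions.
#' @examples
#' similarity("ACGTA", "ACGTT")  # 0.8
#' @export
similarity <- function(probe, window) {
    if (nchar(probe) != nchar(window))
        stop("probe and window lengths differ", call. = FALSE)
    mean(strsplit(probe, "")[[1]] == strsplit(window, "")[[1]])
}

.flatten_database <- function(database) {
    if (inherits(database, "taxon_group")) database <- list(database)
    if (inherits(database, "curation_result")) database <- database$groups
    ids <- character(0); taxa <- character(0); seqs <- character(0)
    for (g in database) {
        stopifnot(inherits(g, "taxon_group"))
        ids <- c(ids, g$members$id)
        taxa <- c(taxa, rep(g$taxon, nrow(g$members)))
        seqs <- c(seqs, g$members$sequence)
    }
    data.frame(id = ids, taxon = taxa, sequence = seqs,
               stringsAsFactors = FALSE)
}

#' Precompute a seed index over a reference database
#'
#' Indexes every seed-width substring of every database sequence on both
#' strands, so that repeated probe screens against the same database are
#' fast.  The index is tied to one seed width; screening validates it.
#'
#' @param database List of `taxon_group` objects (or a `curation_result`).
#' @param probe_length Probe length l the index will serve.
#' @param specificity_threshold Similarity threshold S (sets the allowed
#'   mismatches and hence the seed width).
#' @return A `screen_index` object.
#' @export
build_screen_index <- function(database, probe_length = 25L,
                               specificity_threshold = 0.88) {
    flat <- .flatten_database(database)
    k <- .allowed_mismatches(probe_length, specificity_threshold)
    w <- .seed_width(probe_length, k)
    meta <- data.frame(
        subject_id = rep(flat$id, each = 2L),
        subject_taxon = rep(flat$taxon, each = 2L),
        strand = rep(c("+", "-"), nrow(flat)),
        length = rep(nchar(flat$sequence), each = 2L),
        stringsAsFactors = FALSE)
    texts <- character(nrow(meta))
    texts[meta$strand == "+"] <- flat$sequence
    texts[meta$strand == "-"] <- reverse_complement(flat$sequence)
    chars <- strsplit(texts, "")

    kmer <- character(0); text_i <- integer(0); pos <- integer(0)
    for (t in seq_along(texts)) {
        L <- meta$length[t]
        if (L < w) next
        p <- seq_len(L - w + 1L)
        kmer <- c(kmer, substring(texts[t], p, p + w - 1L))
        text_i <- c(text_i, rep.int(t, length(p)))
        pos <- c(pos, p)
    }
    keys <- unique(kmer)
    grp <- match(kmer, keys)
    ord <- order(grp, method = "radix")
    cnt <- tabulate(grp, length(keys))
    ends <- cumsum(cnt)
    starts <- ends - cnt + 1L
    structure(list(meta = meta, chars = chars,
                   keys = keys, ord = ord,
                   key_start = starts, key_end = ends,
                   entry_text = text_i, entry_pos = pos,
                   seed_width = w, probe_length = as.integer(probe_length),
                   specificity_threshold = specificity_threshold),
              class = "screen_index")
}

#' @export
print.screen_index <- function(x, ...) {
    cat(sprintf(paste0("<screen_index> %d sequence(s) x 2 strands, ",
                       "seed width %d, l = %d, S = %.2f\n"),
                nrow(x$meta) / 2L, x$seed_width, x$probe_length,
                x$specificity_threshold))
    invisible(x)
}

.empty_hits <- function() {
    data.frame(probe_expansion = character(0), subject_id = character(0),
               subject_taxon = character(0), strand = character(0),
               position = integer(0), similarity = numeric(0),
               n_mismatches = integer(0), mismatch_positions = character(0),
               stringsAsFactors = FALSE)
}

#' Find cross-hybridizations of one probe expansion
#'
#' Reports every ungapped window (both strands) of every non-target
#' database sequence whose similarity to the expansion is at least the
#' specificity threshold, with the 1-based probe offsets of the
#' mismatches.  Positions are reported in forward-strand coordinates of
#' the subject.
#'
#' @param expansion A plain ACGT string of length `probe_length`.
#' @param database List of `taxon_group` objects (ignored if `index`
#'   given).
#' @param target_taxon Hits within this taxon are excluded (set to `NA`
#'   or use `include_target = TRUE` to keep them for auditing).
#' @param params A [design_parameters()] object.
#' @param index Optional prebuilt [build_screen_index()] for `database`.
#' @param include_target Keep target-taxon hits?
#' @return Hit data.frame: probe_expansion, subject_id, subject_taxon,
#'   strand, position, similarity, n_mismatches, mismatch_positions
#'   (comma-joined 1-based probe offsets); sorted for determinism.
#' @export
find_cross_hybridizations <- function(expansion, database = NULL,
                                      target_taxon = NA_character_,
                                      params = design_parameters(),
                                      index = NULL,
                                      include_target = FALSE) {
    l <- nchar(expansion)
    pc <- strsplit(expansion, "")[[1]]
    if (!all(pc %in% c("A", "C", "G", "T")))
        stop("expansion must be a plain ACGT string", call. = FALSE)
    S <- params$specificity_threshold
    k <- .allowed_mismatches(l, S)
    w <- .seed_width(l, k)
    if (is.null(index)) {
        if (is.null(database)) stop("need a database or an index",
                                    call. = FALSE)
        index <- build_screen_index(database, l, S)
    }
    if (index$seed_width != w || index$probe_length != l)
        stop("screen index was built for different parameters",
             call. = FALSE)

    # pigeonhole tiling: k+1 disjoint seeds; a window with <= k mismatches
    # matches at least one seed exactly
    offs <- 1L + (0:k) * w
    cand_t <- integer(0); cand_s <- integer(0)
    for (o in offs) {
        ki <- match(substr(expansion, o, o + w - 1L), index$keys)
        if (is.na(ki)) next
        e <- index$ord[index$key_start[ki]:index$key_end[ki]]
        st <- index$entry_pos[e] - o + 1L
        ti <- index$entry_text[e]
        ok <- st >= 1L & st + l - 1L <= index$meta$length[ti]
        cand_t <- c(cand_t, ti[ok])
        cand_s <- c(cand_s, st[ok])
    }
    if (length(cand_t) > 0L) {
        dup <- duplicated(cand_t * (max(index$meta$length) + 1L) + cand_s)
        cand_t <- cand_t[!dup]; cand_s <- cand_s[!dup]
    }

    rows <- vector("list", length(cand_t))
    nrow_out <- 0L
    for (q in seq_along(cand_t)) {
        t <- cand_t[q]; st <- cand_s[q]
        if (!include_target && !is.na(target_taxon) &&
            index$meta$subject_taxon[t] == target_taxon) next
        win <- index$chars[[t]][st:(st + l - 1L)]
        mis <- which(win != pc)
        if (length(mis) > k) next
        L <- index$meta$length[t]
        posf <- if (index$meta$strand[t] == "-") L - (st + l - 1L) + 1L else st
        nrow_out <- nrow_out + 1L
        rows[[nrow_out]] <- data.frame(
            probe_expansion = expansion,
            subject_id = index$meta$subject_id[t],
            subject_taxon = index$meta$subject_taxon[t],
            strand = index$meta$strand[t],
            position = as.integer(posf),
            similarity = (l - length(mis)) / l,
            n_mismatches = length(mis),
            mismatch_positions = paste(mis, collapse = ","),
            stringsAsFactors = FALSE)
    }
    if (nrow_out == 0L) return(.empty_hits())
    hits <- do.call(rbind, rows[seq_len(nrow_out)])
    hits[order(hits$subject_id, hits$strand, hits$position,
               method = "radix"), , drop = FALSE]
}

#' Evaluate a degenerate probe: expansion classes and specificity
#'
#' Expands the probe, labels each expansion known or explorative against
#' its own group, screens every expansion against the database, and sums
#' non-target cross-hybridizations over all expansions.  The probe is
#' accepted when the total does not exceed `max_cross_hyb`.
#'
#' @param probe One-row probe data.frame from [enumerate_probes()].
#' @param group The probe's `taxon_group`.
#' @param database List of `taxon_group` objects (ignored if `index`
#'   given).
#' @param params A [design_parameters()] object.
#' @param index Optional prebuilt [build_screen_index()].
#' @return A `probe_report`: probe row, per-expansion table (sequence,
#'   label, cross_hyb_count), full hit table, total, and status
#'   (`accepted` / `rejected_cross_hyb`).
#' @export
evaluate_probe <- function(probe, group, database = NULL,
                           params = design_parameters(), index = NULL) {
    cls <- classify_expansions(probe, group,
                               cap = max(params$max_degeneracy,
                                         degeneracy_of(probe$sequence[1L])))
    ex <- c(cls$known, cls$explorative)
    label <- c(rep("known", length(cls$known)),
               rep("explorative", length(cls$explorative)))
    ord <- order(ex, method = "radix")
    ex <- ex[ord]; label <- label[ord]
    hit_list <- lapply(ex, find_cross_hybridizations,
                       database = database, target_taxon = group$taxon,
                       params = params, index = index)
    counts <- vapply(hit_list, nrow, integer(1))
    hits <- do.call(rbind, c(hit_list, list(.empty_hits())))
    total <- sum(counts)
    structure(list(probe = probe,
                   expansions = data.frame(sequence = ex, label = label,
                                           cross_hyb_count = counts,
                                           stringsAsFactors = FALSE),
                   hits = hits,
                   total_cross_hyb = total,
                   status = if (total > params$max_cross_hyb)
                       "rejected_cross_hyb" else "accepted"),
              class = "probe_report")
}

#' @export
print.probe_report <- function(x, ...) {
    cat(sprintf(paste0("<probe_report> %s @%d %s (deg %d): %s, ",
                       "%d known + %d explorative expansion(s), ",
                       "%d cross-hybridization(s)\n"),
                x$probe$taxon, x$probe$start, x$probe$sequence,
                as.integer(x$probe$degeneracy), x$status,
                sum(x$expansions$label == "known"),
                sum(x$expansions$label == "explorative"),
                x$total_cross_hyb))
    invisible(x)
}

#' Screen a table of probes against the reference database
#'
#' The per-job worker of the pipeline: evaluates each probe with
#' [evaluate_probe()] and returns flat result tables.
#'
#' @param probes Probe data.frame (rows from [enumerate_probes()]).
#' @param database List of `taxon_group` objects, used both as the probe's
#'   own group lookup (by taxon) and as the screening database.
#' @param params A [design_parameters()] object.
#' @param index Optional prebuilt [build_screen_index()] for `database`.
#' @return List of two data.frames: `results` (taxon, start, sequence,
#'   degeneracy, expansion, label, status, cross_hyb_count) with one row
#'   per expansion, and `hits` (probe coordinates plus the
#'   [find_cross_hybridizations()] columns).
#' @export
screen_probes <- function(probes, database, params = design_parameters(),
                          index = NULL) {
    if (inherits(database, "curation_result")) database <- database$groups
    if (is.null(index))
        index <- build_screen_index(database, params$probe_length,
                                    params$specificity_threshold)
    taxa <- vapply(database, `[[`, character(1), "taxon")
    if (nrow(probes) == 0L)
        return(list(results = data.frame(
                        taxon = character(0), start = integer(0),
                        sequence = character(0), degeneracy = numeric(0),
                        expansion = character(0), label = character(0),
                        status = character(0), cross_hyb_count = integer(0),
                        stringsAsFactors = FALSE),
                    hits = cbind(data.frame(taxon = character(0),
                                            start = integer(0),
                                            sequence = character(0),
                                            stringsAsFactors = FALSE),
                                 .empty_hits())))
    res <- vector("list", nrow(probes))
    hit <- vector("list", nrow(probes))
    for (i in seq_len(nrow(probes))) {
        p <- probes[i, , drop = FALSE]
        g <- database[[match(p$taxon, taxa)]]
        if (is.null(g)) stop("no group for taxon '", p$taxon, "'",
                             call. = FALSE)
        rep_i <- evaluate_probe(p, g, params = params, index = index)
        res[[i]] <- data.frame(taxon = p$taxon, start = p$start,
                               sequence = p$sequence,
                               degeneracy = p$degeneracy,
                               expansion = rep_i$expansions$sequence,
                               label = rep_i$expansions$label,
                               status = rep_i$status,
                               cross_hyb_count =
                                   rep_i$expansions$cross_hyb_count,
                               stringsAsFactors = FALSE)
        if (nrow(rep_i$hits) > 0L)
            hit[[i]] <- cbind(data.frame(taxon = p$taxon, start = p$start,
                                         sequence = p$sequence,
                                         stringsAsFactors = FALSE),
                              rep_i$hits, row.names = NULL)
    }
    hit <- hit[!vapply(hit, is.null, logical(1))]
    empty_hits <- cbind(data.frame(taxon = character(0),
                                   start = integer(0),
                                   sequence = character(0),
                                   stringsAsFactors = FALSE),
                        .empty_hits())
    list(results = do.call(rbind, res),
         hits = if (length(hit) > 0L) do.call(rbind, hit) else empty_hits)
}
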