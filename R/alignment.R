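# Multiple alignment of taxon groups.
#
# One deterministic dynamic-programming core (src/align.cpp) serves every
# alignment operation: pairwise global/local alignment, progressive group
# alignment along a single-linkage guide tree, and profile-profile merging
# of subgroup alignments for large groups.  Scoring is linear-gap
# (match +1, mismatch -1, gap -2 by default) with fixed tie-breaking
# (diagonal, then up, then left), so every result is reproducible.

.default_scoring <- list(match = 1, mismatch = -1, gap = -2)

#' Construct an alignment object
#'
#' @param ids Character vector of row ids (unique).
#' @param rows Character vector of gapped sequences, equal lengths.
#' @return An object of class `dna_alignment` with elements `ids`, `rows`
#'   and `columns`.
#' @export
new_alignment <- function(ids, rows) {
    stopifnot(length(ids) == length(rows), length(rows) >= 1L)
    if (anyDuplicated(ids)) stop("duplicate row ids", call. = FALSE)
    w <- unique(nchar(rows))
    if (length(w) != 1L)
        stop("alignment rows have unequal lengths", call. = FALSE)
    structure(list(ids = as.character(ids), rows = as.character(rows),
                   columns = w),
              class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
    cat(sprintf("<dna_alignment> %d row(s) x %d column(s)\n",
                length(x$ids), x$columns))
    invisible(x)
}

.aln_chars <- function(aln) {
    matrix(unlist(strsplit(aln$rows, ""), use.names = FALSE),
           nrow = length(aln$rows), byrow = TRUE)
}

# 4 x C frequency profile of a set of gapped rows; IUPAC codes spread
# 1/|set| over their bases, gaps contribute nothing.
.profile_of <- function(rows) {
    C <- nchar(rows[1L])
    M <- matrix(unlist(strsplit(rows, ""), use.names = FALSE),
                nrow = length(rows), byrow = TRUE)
    P <- matrix(0, 4L, C, dimnames = list(c("A", "C", "G", "T"), NULL))
    map <- .iupac_map()
    for (ch in setdiff(unique(as.vector(M)), "-")) {
        bases <- strsplit(unname(map[ch]), "")[[1]]
        cnt <- if (nrow(M) == 1L) as.numeric(M[1L, ] == ch) else
            colSums(M == ch)
        P[bases, ] <- P[bases, , drop = FALSE] + cnt / length(bases)
    }
    P / length(rows)
}

.apply_map <- function(chars, cols) {
    out <- rep("-", length(cols))
    hit <- cols > 0L
    out[hit] <- chars[cols[hit]]
    paste(out, collapse = "")
}

#' Optimal pairwise alignment
#'
#' Needleman-Wunsch (`mode = "global"`) or Smith-Waterman
#' (`mode = "local"`) alignment of two IUPAC sequences under linear gap
#' penalties with deterministic tie-breaking.
#'
#' @param a,b Sequences (IUPAC strings).
#' @param mode `"global"` or `"local"`.
#' @param scoring List with `match`, `mismatch`, `gap`.
#' @return List with `score`, gapped strings `a_aln`/`b_aln` (for local
#'   mode, the aligned core only; possibly empty), `matches` (identical
#'   aligned characters) and `columns`.
#' @examples
#' pairwise_align("ACGT", "AGT")$score  # 1
#' @export
pairwise_align <- function(a, b, mode = c("global", "local"),
                           scoring = .default_scoring) {
    mode <- match.arg(mode)
    stopifnot(nzchar(a), nzchar(b))
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    .check_iupac(ca); .check_iupac(cb)
    res <- profile_align_cpp(.profile_of(a), .profile_of(b),
                             scoring$match, scoring$mismatch, scoring$gap,
                             mode == "local")
    both <- res$a_cols > 0L & res$b_cols > 0L
    matches <- sum(ca[res$a_cols[both]] == cb[res$b_cols[both]])
    list(score = res$score,
         a_aln = .apply_map(ca, res$a_cols),
         b_aln = .apply_map(cb, res$b_cols),
         matches = matches,
         columns = length(res$a_cols))
}

# Merge two alignments by profile-profile global alignment.  Only whole gap
# columns are inserted, so the relative column order of each input is
# preserved.
.merge_two <- function(A, B, scoring = .default_scoring) {
    res <- profile_align_cpp(.profile_of(A$rows), .profile_of(B$rows),
                             scoring$match, scoring$mismatch, scoring$gap,
                             FALSE)
    MA <- .aln_chars(A); MB <- .aln_chars(B)
    rows <- c(vapply(seq_along(A$ids),
                     function(i) .apply_map(MA[i, ], res$a_cols),
                     character(1)),
              vapply(seq_along(B$ids),
                     function(i) .apply_map(MB[i, ], res$b_cols),
                     character(1)))
    new_alignment(c(A$ids, B$ids), rows)
}

.group_seqs <- function(x) {
    if (inherits(x, "taxon_group"))
        structure(x$members$sequence, names = x$members$id)
    else if (is.data.frame(x))
        structure(x$sequence, names = x$id)
    else if (is.character(x) && !is.null(names(x)))
        x
    else stop("expected a taxon_group, record data.frame or named ",
              "character vector", call. = FALSE)
}

# expected pairwise score between two IUPAC codes under the profile
# scoring model: match * P(same base) + mismatch * P(different base)
.subs_table <- function(scoring) {
    map <- .iupac_map()
    sets <- strsplit(unname(map), "")
    S <- matrix(0, 15L, 15L)
    for (x in 1:15) for (y in 1:15) {
        dot <- length(intersect(sets[[x]], sets[[y]])) /
            (length(sets[[x]]) * length(sets[[y]]))
        S[x, y] <- scoring$match * dot + scoring$mismatch * (1 - dot)
    }
    S
}

# All-pairs global-alignment identity (matches / alignment columns) and
# gap-free shared-column coverage relative to the shorter sequence.
# Same DP, scoring and tie-breaks as the profile aligner, but computed in
# one compiled pass over all pairs since only the statistics are needed.
.pairwise_identity <- function(seqs, scoring = .default_scoring) {
    n <- length(seqs)
    idy <- matrix(1, n, n)
    cov <- matrix(1, n, n)
    if (n < 2L) return(list(identity = idy, coverage = cov))
    map <- .iupac_map()
    enc <- lapply(strsplit(seqs, ""), function(ch)
        match(ch, names(map)) - 1L)
    st <- pairwise_stats_cpp(enc, .subs_table(scoring), scoring$gap)
    q <- 0L
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        q <- q + 1L
        idy[i, j] <- idy[j, i] <- st$matches[q] / st$columns[q]
        cov[i, j] <- cov[j, i] <-
            st$paired[q] / min(nchar(seqs[i]), nchar(seqs[j]))
    }
    list(identity = idy, coverage = cov)
}

#' Progressive multiple alignment of a group
#'
#' Sequences are merged along a single-linkage guide tree built from
#' all-pairs global-alignment identity; sequences and intermediate
#' alignments are combined by profile-profile alignment.  Stripping gaps
#' from any output row reproduces the input sequence exactly.
#'
#' @param x A `taxon_group`, record data.frame, or named character vector.
#' @param scoring List with `match`, `mismatch`, `gap`.
#' @return A `dna_alignment`; rows are in input order.
#' @export
progressive_align <- function(x, scoring = .default_scoring) {
    seqs <- .group_seqs(x)
    n <- length(seqs)
    stopifnot(n >= 1L)
    ids <- names(seqs)
    if (n == 1L) return(new_alignment(ids, unname(seqs)))
    leaves <- lapply(seq_len(n),
                     function(i) new_alignment(ids[i], unname(seqs[i])))
    if (n == 2L) {
        out <- .merge_two(leaves[[1L]], leaves[[2L]], scoring)
    } else {
        D <- 1 - .pairwise_identity(seqs, scoring)$identity
        hc <- hclust(as.dist(D), method = "single")
        nodes <- vector("list", n - 1L)
        pick <- function(k) if (k < 0L) leaves[[-k]] else nodes[[k]]
        for (s in seq_len(n - 1L))
            nodes[[s]] <- .merge_two(pick(hc$merge[s, 1L]),
                                     pick(hc$merge[s, 2L]), scoring)
        out <- nodes[[n - 1L]]
    }
    ord <- match(ids, out$ids)
    new_alignment(out$ids[ord], out$rows[ord])
}

#' Single-linkage subgrouping of highly similar sequences
#'
#' Two sequences link when their global-alignment identity is at least
#' `threshold` over at least `coverage` of the shorter sequence's length;
#' subgroups are the connected components of the link graph.  Used to
#' split large groups before alignment.
#'
#' @param x A `taxon_group`, record data.frame, or named character vector.
#' @param threshold Identity threshold (default 0.98).
#' @param coverage Coverage threshold (default 0.98).
#' @param scoring Alignment scoring parameters.
#' @return List with `subgroups` (list of integer index vectors, ordered by
#'   first member) and `membership` (integer vector).
#' @export
cluster_subgroups <- function(x, threshold = 0.98, coverage = 0.98,
                              scoring = .default_scoring) {
    seqs <- .group_seqs(x)
    n <- length(seqs)
    comp <- seq_len(n)
    if (n >= 2L) {
        pw <- .pairwise_identity(seqs, scoring)
        for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
            if (pw$identity[i, j] >= threshold &&
                pw$coverage[i, j] >= coverage) {
                old <- comp[j]
                comp[comp == old] <- comp[i]
            }
        }
    }
    membership <- match(comp, unique(comp))
    subgroups <- split(seq_len(n), membership)
    names(subgroups) <- NULL
    list(subgroups = subgroups, membership = membership,
         identity_threshold = threshold)
}

#' Merge multiple alignments into one
#'
#' Iterative profile-profile alignment: each input alignment's columns map
#' order-preservingly into the output (only whole gap columns are
#' inserted), and gap-stripping any row still reproduces its original
#' sequence.
#'
#' @param alignments List of `dna_alignment` objects with disjoint row ids.
#' @param scoring Alignment scoring parameters.
#' @return A single `dna_alignment`.
#' @export
merge_alignments <- function(alignments, scoring = .default_scoring) {
    stopifnot(is.list(alignments), length(alignments) >= 1L)
    ids <- unlist(lapply(alignments, `[[`, "ids"))
    if (anyDuplicated(ids))
        stop("duplicate row ids across alignments", call. = FALSE)
    out <- alignments[[1L]]
    for (k in seq_along(alignments)[-1L])
        out <- .merge_two(out, alignments[[k]], scoring)
    out
}

#' Align a taxon group, with subgroup merging for large groups
#'
#' Groups of at most `large_group_threshold` sequences are aligned
#' progressively in one pass.  Larger groups are first split into
#' subgroups of highly similar sequences ([cluster_subgroups()] at 98%
#' identity), each subgroup aligned independently, and the subgroup
#' alignments merged by profile-profile alignment.
#'
#' @param x A `taxon_group`, record data.frame, or named character vector.
#' @param large_group_threshold Size above which the split-and-merge
#'   strategy is used (default 100).
#' @param scoring Alignment scoring parameters.
#' @return A `dna_alignment`; rows are in input order.
#' @export
align_group <- function(x, large_group_threshold = 100L,
                        scoring = .default_scoring) {
    seqs <- .group_seqs(x)
    if (length(seqs) <= large_group_threshold)
        return(progressive_align(seqs, scoring))
    cl <- cluster_subgroups(seqs, scoring = scoring)
    subalns <- lapply(cl$subgroups,
                      function(ix) progressive_align(seqs[ix], scoring))
    out <- merge_alignments(subalns, scoring)
    ord <- match(names(seqs), out$ids)
    new_alignment(out$ids[ord], out$rows[ord])
}

#' Pairwise distance matrix from an alignment
#'
#' Distance between two rows is one minus the fraction of identical
#' characters over columns where neither row has a gap; a pair with no
#' shared gap-free column has distance 1.
#'
#' @param aln A `dna_alignment` with at least 2 rows.
#' @return Symmetric numeric matrix with zero diagonal, values in `[0, 1]`,
#'   dimnames set to row ids.
#' @export
distance_matrix <- function(aln) {
    stopifnot(inherits(aln, "dna_alignment"), length(aln$ids) >= 2L)
    M <- .aln_chars(aln)
    n <- nrow(M)
    D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
    gap <- M == "-"
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        shared <- !gap[i, ] & !gap[j, ]
        D[i, j] <- D[j, i] <- if (!any(shared)) 1 else
            1 - mean(M[i, shared] == M[j, shared])
    }
    D
}

#' Read / write aligned FASTA
#'
#' @param path FASTA file of equal-length gapped rows.
#' @return `read_alignment`: a `dna_alignment`.
#' @export
read_alignment <- function(path) {
    rec <- read_fasta(path)
    new_alignment(rec$id, rec$sequence)
}

#' @param aln A `dna_alignment`.
#' @rdname read_alignment
#' @export
write_alignment <- function(aln, path) {
    write_fasta(structure(aln$rows, names = aln$ids), path)
}
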