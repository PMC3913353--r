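# Synthetic fixture generation: genus-like sequence groups with planted
# defects (short entries, exact duplicates, reverse-complemented entries,
# divergent outliers) and a ground-truth manifest, so that every pipeline
# stage can be exercised and audited without any external download.

#' Specification of a synthetic group fixture
#'
#' The generator emulates a genus-level SSU collection: each group's
#' sequences descend from a group template (itself mutated away from a
#' common ancestor by `divergence`), with independent per-site
#' substitutions at `substitution_rate` and sparse `N` injection at
#' `ambiguity_rate`.  Per group it also plants, in this order after the
#' good members: `n_duplicates` exact copies of the first member,
#' `n_short` truncated entries (70% of the template length), and
#' `n_outliers` heavily mutated entries (`outlier_rate`).  `n_reversed`
#' of the good members are stored reverse-complemented and must be
#' flipped back by curation.  A distinct 25-base tag is embedded in each
#' group template so that each group carries probe windows with no
#' counterpart in other groups.
#'
#' @param n_groups Number of groups (default 10).
#' @param sequences_per_group Good members per group (default 10).
#' @param template_length Template length in bases (default 1300, inside
#'   the default curation window for prokaryotic 16S).
#' @param substitution_rate Within-group per-site substitution rate
#'   (default 0.02).
#' @param divergence Ancestor-to-template per-site substitution rate
#'   (default 0.10).
#' @param ambiguity_rate Per-site N-injection rate (default 0.001; kept
#'   far below the 1% curation bound).
#' @param n_duplicates,n_reversed,n_short,n_outliers Planted defect counts
#'   per group (defaults 1 each).
#' @param outlier_rate Outlier per-site substitution rate (default 0.35).
#' @param seed RNG seed; the fixture is a pure function of the spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_groups = 10L, sequences_per_group = 10L,
                         template_length = 1300L,
                         substitution_rate = 0.02, divergence = 0.10,
                         ambiguity_rate = 0.001,
                         n_duplicates = 1L, n_reversed = 1L,
                         n_short = 1L, n_outliers = 1L,
                         outlier_rate = 0.35, seed = 1L) {
    rates <- c(substitution_rate, divergence, ambiguity_rate, outlier_rate)
    if (any(rates < 0 | rates > 1))
        stop("rates must lie in [0, 1]", call. = FALSE)
    if (n_groups < 1L || sequences_per_group < 1L || template_length < 30L)
        stop("need >= 1 group, >= 1 sequence per group and a template of ",
             ">= 30 bases", call. = FALSE)
    if (n_reversed > sequences_per_group)
        stop("cannot reverse more members than the group has",
             call. = FALSE)
    if (any(c(n_duplicates, n_short, n_outliers) > sequences_per_group))
        stop("planted defect counts cannot exceed the group size",
             call. = FALSE)
    structure(list(n_groups = as.integer(n_groups),
                   sequences_per_group = as.integer(sequences_per_group),
                   template_length = as.integer(template_length),
                   substitution_rate = substitution_rate,
                   divergence = divergence,
                   ambiguity_rate = ambiguity_rate,
                   n_duplicates = as.integer(n_duplicates),
                   n_reversed = as.integer(n_reversed),
                   n_short = as.integer(n_short),
                   n_outliers = as.integer(n_outliers),
                   outlier_rate = outlier_rate,
                   seed = as.integer(seed)),
              class = "fixture_spec")
}

.random_seq <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_seq <- function(seq, rate) {
    if (rate <= 0) return(seq)
    chars <- strsplit(seq, "")[[1]]
    hit <- which(runif(length(chars)) < rate)
    if (length(hit) > 0L) {
        # substitute to one of the three other bases, uniformly
        shift <- sample.int(3L, length(hit), replace = TRUE)
        cur <- match(chars[hit], c("A", "C", "G", "T"))
        chars[hit] <- c("A", "C", "G", "T")[(cur - 1L + shift) %% 4L + 1L]
    }
    paste(chars, collapse = "")
}

.inject_n <- function(seq, rate, max_frac = 0.009) {
    if (rate <= 0) return(seq)
    chars <- strsplit(seq, "")[[1]]
    hit <- which(runif(length(chars)) < rate)
    cap <- floor(max_frac * length(chars))
    if (length(hit) > cap) hit <- hit[seq_len(cap)]
    chars[hit] <- "N"
    paste(chars, collapse = "")
}

# distinct per-group 25-mer tags, pairwise Hamming distance >= 10
.make_tags <- function(n, len = 25L, min_dist = 10L) {
    tags <- character(0)
    while (length(tags) < n) {
        cand <- .random_seq(len)
        ok <- all(vapply(tags, function(t)
            sum(strsplit(t, "")[[1]] != strsplit(cand, "")[[1]]) >= min_dist,
            logical(1)))
        if (ok) tags <- c(tags, cand)
    }
    tags
}

#' Generate a synthetic fixture on disk
#'
#' Deterministic under the spec's seed: the same spec always yields
#' byte-identical files.  Writes `sequences.fasta`, `taxonomy.tsv`,
#' `reference.fasta` (the common ancestor, for orientation) and
#' `manifest.tsv` (ground truth: expected disposition and reorientation
#' flag per record) into `dir`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a list with `spec`, file `paths`, the ground-truth
#'   `manifest` data.frame and the per-group planted `tags`
#'   (taxon, position, tag).
#' @export
generate_fixture <- function(spec = fixture_spec(), dir) {
    stopifnot(inherits(spec, "fixture_spec"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    old_seed <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old_seed)) {
            if (exists(".Random.seed", globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old_seed, globalenv())
    })
    set.seed(spec$seed)

    ancestor <- .random_seq(spec$template_length)
    tag_pos <- spec$template_length %/% 2L
    tags <- .make_tags(spec$n_groups)

    ids <- character(0); seqs <- character(0); taxa <- character(0)
    roles <- character(0); expect <- character(0); reor <- logical(0)
    short_len <- floor(0.7 * spec$template_length)

    for (g in seq_len(spec$n_groups)) {
        tx <- sprintf("genus%02d", g)
        template <- .mutate_seq(ancestor, spec$divergence)
        substr(template, tag_pos, tag_pos + nchar(tags[g]) - 1L) <- tags[g]

        members <- character(spec$sequences_per_group)
        for (i in seq_len(spec$sequences_per_group))
            members[i] <- .inject_n(.mutate_seq(template,
                                                spec$substitution_rate),
                                    spec$ambiguity_rate)
        rev_ix <- if (spec$n_reversed > 0L)
            seq(spec$sequences_per_group - spec$n_reversed + 1L,
                spec$sequences_per_group) else integer(0)

        for (i in seq_len(spec$sequences_per_group)) {
            flipped <- i %in% rev_ix
            ids <- c(ids, sprintf("%s_s%02d", tx, i))
            seqs <- c(seqs, if (flipped) reverse_complement(members[i])
                      else members[i])
            taxa <- c(taxa, tx)
            roles <- c(roles, if (flipped) "reversed" else "good")
            expect <- c(expect, "kept")
            reor <- c(reor, flipped)
        }
        for (k in seq_len(spec$n_duplicates)) {
            ids <- c(ids, sprintf("%s_dup%02d", tx, k))
            seqs <- c(seqs, members[1L])
            taxa <- c(taxa, tx)
            roles <- c(roles, "duplicate")
            expect <- c(expect, "removed_duplicate")
            reor <- c(reor, FALSE)
        }
        for (k in seq_len(spec$n_short)) {
            ids <- c(ids, sprintf("%s_short%02d", tx, k))
            seqs <- c(seqs, substr(template, 1L, short_len))
            taxa <- c(taxa, tx)
            roles <- c(roles, "short")
            expect <- c(expect, "rejected_length")
            reor <- c(reor, FALSE)
        }
        for (k in seq_len(spec$n_outliers)) {
            ids <- c(ids, sprintf("%s_out%02d", tx, k))
            seqs <- c(seqs, .mutate_seq(template, spec$outlier_rate))
            taxa <- c(taxa, tx)
            roles <- c(roles, "outlier")
            expect <- c(expect, "removed_inhomogeneous")
            reor <- c(reor, FALSE)
        }
    }

    manifest <- data.frame(id = ids, taxon = taxa, role = roles,
                           expected_disposition = expect,
                           expected_reoriented = reor,
                           stringsAsFactors = FALSE)
    paths <- list(fasta = file.path(dir, "sequences.fasta"),
                  taxonomy = file.path(dir, "taxonomy.tsv"),
                  reference = file.path(dir, "reference.fasta"),
                  manifest = file.path(dir, "manifest.tsv"))
    write_fasta(structure(seqs, names = ids), paths$fasta)
    write.table(data.frame(id = ids, kingdom = "prokaryote", taxon = taxa,
                           stringsAsFactors = FALSE),
                paths$taxonomy, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_fasta(c(reference = ancestor), paths$reference)
    write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(list(spec = spec, paths = paths, manifest = manifest,
                   tags = data.frame(taxon = sprintf("genus%02d",
                                                     seq_len(spec$n_groups)),
                                     position = tag_pos, tag = tags,
                                     stringsAsFactors = FALSE)))
}
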