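rec1 <- function(seq, kingdom = "prokaryote", taxon = "Genus") {
    data.frame(id = "r1", sequence = seq, kingdom = kingdom, taxon = taxon,
               reoriented = FALSE, stringsAsFactors = FALSE)
}

test_that("quality filter applies the length, taxon and unknown rules in order", {
    set.seed(5)
    expect_identical(filter_sequence(rec1(random_dna(1150))),
                     "rejected_length")
    expect_identical(filter_sequence(rec1(random_dna(1650))),
                     "rejected_length")
    expect_identical(filter_sequence(rec1(random_dna(1650), "fungi")),
                     "kept")
    expect_identical(filter_sequence(rec1(random_dna(1300), taxon = NA)),
                     "rejected_taxon")

    # 14 scattered N in 1300 bases: 1.077% >= 1%
    chars <- strsplit(random_dna(1300), "")[[1]]
    chars[seq(10, by = 90, length.out = 14)] <- "N"
    expect_identical(filter_sequence(rec1(paste(chars, collapse = ""))),
                     "rejected_unknown_fraction")

    # a single run of exactly 5 N passes; 6 fails
    base <- random_dna(1300)
    five <- paste0(substr(base, 1, 600), "NNNNN", substr(base, 606, 1300))
    six <- paste0(substr(base, 1, 600), "NNNNNN", substr(base, 607, 1300))
    expect_identical(filter_sequence(rec1(five)), "kept")
    expect_identical(filter_sequence(rec1(six)), "rejected_unknown_run")

    expect_error(filter_sequence(rec1(random_dna(1300), "archaea")),
                 "unknown kingdom")
})

test_that("orientation flips a reverse-complemented record and is idempotent", {
    set.seed(17)
    ref <- random_dna(400)
    fwd <- rec1(ref)
    expect_identical(orient_sequence(fwd, ref), fwd)

    flipped <- rec1(rc_plain(ref))
    out <- orient_sequence(flipped, ref)
    expect_identical(out$sequence, ref)
    expect_true(out$reoriented)

    # 5% substitutions then reverse complement: still detected and flipped
    mut <- mutate_dna(ref, 20)
    out2 <- orient_sequence(rec1(rc_plain(mut)), ref)
    expect_identical(out2$sequence, mut)
    expect_true(out2$reoriented)
    expect_identical(orient_sequence(out2, ref), out2)

    expect_error(orient_sequence(fwd, ""), "empty reference")
})

test_that("dereplication removes identical and contained sequences", {
    g <- make_group("g", c("ACGTACGT", "ACGTACGT"))
    out <- dereplicate_group(g)
    expect_equal(length(out), 1)
    expect_identical(attr(out, "removed_ids"), "g_02")

    g2 <- make_group("g", c("ACGTACGT", "GTAC"))
    out2 <- dereplicate_group(g2)
    expect_identical(out2$members$sequence, "ACGTACGT")

    g3 <- make_group("g", c("ACGT", "ACGA"))
    expect_equal(length(dereplicate_group(g3)), 2)

    # idempotence and the no-substring-pair invariant on random groups,
    # checked against a brute-force containment scan
    set.seed(29)
    for (rep in 1:10) {
        base <- random_dna(40)
        seqs <- c(base,
                  substr(base, sample(1:10, 1), sample(30:40, 1)),
                  mutate_dna(base, 2), base,
                  random_dna(25))
        g <- make_group("g", seqs)
        d1 <- dereplicate_group(g)
        d2 <- dereplicate_group(d1)
        expect_identical(d2$members$sequence, d1$members$sequence)
        kept <- d1$members$sequence
        for (i in seq_along(kept)) for (j in seq_along(kept))
            if (i != j) expect_false(grepl(kept[i], kept[j], fixed = TRUE))
        # every removed sequence really is contained in some kept one
        removed <- setdiff(g$members$id, d1$members$id)
        for (id in removed) {
            s <- g$members$sequence[g$members$id == id]
            expect_true(any(grepl(s, kept, fixed = TRUE)))
        }
    }
})

test_that("homogeneity screening drops a divergent outlier, keeps tight groups", {
    set.seed(37)
    base <- random_dna(300)
    tight <- vapply(1:10, function(i) mutate_dna(base, 3), character(1))
    g <- homogeneity_filter(make_group("g", tight))
    expect_equal(length(g), 10)

    ident <- homogeneity_filter(make_group("g", rep(base, 6)))
    expect_equal(length(ident), 6)

    seqs <- c(vapply(1:9, function(i) mutate_dna(base, 3), character(1)),
              mutate_dna(base, 100))     # >= 30% divergent outlier
    out <- homogeneity_filter(make_group("g", seqs))
    expect_equal(length(out), 9)
    expect_identical(attr(out, "removed_ids"), "g_10")

    # brute-force check: of all 2-partitions, the one minimizing total
    # within-cluster variance of the distance embedding isolates the outlier
    D <- distance_matrix(progressive_align(make_group("g", seqs)))
    best <- NULL; best_v <- Inf
    for (mask in 1:(2^10 - 2)) {
        part <- as.logical(bitwAnd(mask, 2^(0:9)))
        v <- 0
        for (side in list(part, !part)) {
            if (sum(side) == 0) next
            ctr <- colMeans(D[side, , drop = FALSE])
            v <- v + sum(sweep(D[side, , drop = FALSE], 2, ctr)^2)
        }
        if (v < best_v) { best_v <- v; best <- part }
    }
    expect_true(xor(all(which(best) == 10), all(which(!best) == 10)))

    # never removes more than half
    set.seed(43)
    for (rep in 1:5) {
        seqs <- vapply(1:6, function(i) mutate_dna(base, sample(0:40, 1)),
                       character(1))
        out <- homogeneity_filter(make_group("g", seqs))
        expect_gte(length(out), 3)
    }
})

test_that("database building reports one disposition per record, conserved", {
    fx <- generate_fixture(
        fixture_spec(n_groups = 3, sequences_per_group = 6,
                     template_length = 400, seed = 19),
        withr::local_tempdir())
    rec <- read_fasta(fx$paths$fasta, taxonomy = fx$paths$taxonomy)
    ref <- read_fasta(fx$paths$reference)
    cur <- build_database(rec, ref[1, , drop = FALSE],
                          criteria = curation_criteria(min_length = 300))

    expect_equal(nrow(cur$report), nrow(rec))
    m <- merge(cur$report, fx$manifest, by = "id")
    expect_identical(m$disposition, m$expected_disposition)
    expect_identical(m$reoriented, m$expected_reoriented)

    counts <- curation_counts(cur)
    per_group <- tapply(counts$count, counts$taxon, sum)
    expect_true(all(per_group == 9))   # 6 good + dup + short + outlier

    expect_error(build_database(rec[0, ], ref[1, , drop = FALSE]),
                 "empty input")

    # all records failing the filter: no groups, totals still conserved
    short <- rec
    short$sequence <- substr(short$sequence, 1, 100)
    cur2 <- build_database(short, ref[1, , drop = FALSE],
                           criteria = curation_criteria(min_length = 300))
    expect_length(cur2$groups, 0)
    expect_true(all(cur2$report$disposition == "rejected_length"))
})
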