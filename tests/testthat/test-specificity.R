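test_that("similarity is the identity fraction and the threshold is inclusive", {
    set.seed(83)
    p <- random_dna(25)
    expect_equal(similarity(p, p), 1.0)
    expect_equal(similarity(p, mutate_dna(p, 3)), 0.88)
    expect_equal(similarity(p, mutate_dna(p, 4)), 0.84)
    expect_error(similarity("ACGT", "ACG"), "lengths differ")

    # 3 mismatches count as a cross-hybridization at S = 0.88, 4 do not
    target <- make_group("t", random_dna(200))
    hit3 <- paste0(random_dna(80), mutate_dna(p, 3), random_dna(80))
    hit4 <- paste0(random_dna(80), mutate_dna(p, 4), random_dna(80))
    db <- list(target, make_group("n3", hit3), make_group("n4", hit4))
    h <- find_cross_hybridizations(p, db, "t")
    expect_true(any(h$subject_taxon == "n3" & h$similarity == 0.88))
    expect_false(any(h$subject_taxon == "n4" & h$position == 81))
})

test_that("planted matches are found on the correct strand, self-hits excluded", {
    set.seed(89)
    p <- random_dna(25)
    target <- make_group("t", paste0(random_dna(50), p, random_dna(50)))
    fwd <- make_group("f", paste0(random_dna(30), p, random_dna(40)))
    rev <- make_group("r", paste0(random_dna(30), rc_plain(p),
                                  random_dna(40)))
    h <- find_cross_hybridizations(p, list(target, fwd, rev), "t")
    expect_true(any(h$subject_taxon == "f" & h$strand == "+" &
                    h$similarity == 1.0 & h$position == 31))
    expect_true(any(h$subject_taxon == "r" & h$strand == "-"))
    expect_false(any(h$subject_taxon == "t"))

    # screening a database holding only the target group: no hits at all
    only <- find_cross_hybridizations(p, list(target), "t")
    expect_equal(nrow(only), 0)
})

test_that("seed-and-extend equals the brute-force all-window scan", {
    set.seed(97)
    params <- design_parameters()
    for (rep in 1:12) {
        groups <- lapply(1:3, function(g)
            make_group(paste0("g", g),
                       vapply(1:2, function(i) random_dna(300),
                              character(1))))
        # probes derived from database windows with 0-5 mutations, so that
        # hits at and around the threshold actually occur
        donor <- groups[[sample(3, 1)]]$members$sequence[1]
        st <- sample(nchar(donor) - 24, 1)
        probes <- c(random_dna(25),
                    mutate_dna(substr(donor, st, st + 24), sample(0:5, 1)))
        for (p in probes) {
            got <- find_cross_hybridizations(p, groups, "g1", params)
            want <- oracle_cross_hyb(p, groups, "g1",
                                     params$specificity_threshold)
            expect_equal(nrow(got), nrow(want))
            if (nrow(got) > 0) {
                rownames(got) <- NULL
                expect_identical(got[hit_key_cols], want[hit_key_cols])
                expect_equal(got$similarity, (25 - got$n_mismatches) / 25)
            }
        }
    }
})

test_that("mismatch positions are 1-based probe offsets", {
    set.seed(101)
    p <- random_dna(25)
    pc <- strsplit(p, "")[[1]]
    win <- pc
    win[c(3, 17)] <- vapply(win[c(3, 17)], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    subj <- paste0(random_dna(10), paste(win, collapse = ""), random_dna(10))
    h <- find_cross_hybridizations(p, list(make_group("t", random_dna(60)),
                                           make_group("n", subj)), "t")
    fwd <- h[h$strand == "+" & h$position == 11, ]
    expect_equal(nrow(fwd), 1)
    expect_identical(fwd$mismatch_positions, "3,17")
    expect_equal(fwd$n_mismatches, 2)
})

test_that("probe evaluation sums non-target hits over all expansions", {
    set.seed(103)
    base <- random_dna(120)
    g <- make_group("t", vapply(1:3, function(i) mutate_dna(base, 1),
                                character(1)))
    clean <- make_group("other", random_dna(120))
    probes <- enumerate_probes(
        build_consensus(progressive_align(g), taxon = "t")$consensus,
        design_parameters())
    pr <- evaluate_probe(probes[1, ], g, list(g, clean))
    expect_identical(pr$status, "accepted")
    expect_equal(pr$total_cross_hyb, nrow(pr$hits))
    expect_equal(sum(pr$expansions$cross_hyb_count), pr$total_cross_hyb)
    expect_equal(nrow(pr$expansions), probes$degeneracy[1])

    # a probe is rejected exactly when non-target hits exceed the cap
    p25 <- random_dna(25)
    near <- make_group("near", paste0(
        paste(rep(p25, 3), collapse = random_dna(5)), random_dna(10)))
    tgt <- make_group("t", paste0(random_dna(40), p25, random_dna(40)))
    probe_row <- data.frame(taxon = "t", start = 41, sequence = p25,
                            degeneracy = 1, weight = 1,
                            stringsAsFactors = FALSE)
    n_hits <- nrow(find_cross_hybridizations(p25, list(tgt, near), "t"))
    expect_gte(n_hits, 3)
    strict <- design_parameters(max_cross_hyb = n_hits - 1)
    loose <- design_parameters(max_cross_hyb = n_hits)
    expect_identical(evaluate_probe(probe_row, tgt, list(tgt, near),
                                    strict)$status, "rejected_cross_hyb")
    expect_identical(evaluate_probe(probe_row, tgt, list(tgt, near),
                                    loose)$status, "accepted")
})
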