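test_that("pairwise global alignment is optimal and deterministic", {
    pa <- pairwise_align("ACGT", "ACGT")
    expect_equal(pa$score, 4)
    expect_identical(pa$a_aln, "ACGT")
    expect_identical(pa$b_aln, "ACGT")

    pa <- pairwise_align("ACGT", "AGT")
    expect_equal(pa$score, 1)          # 3 matches - 1 gap
    expect_equal(pa$columns, 4)

    # scores agree with a brute-force recursion on random short pairs
    set.seed(11)
    for (rep in 1:30) {
        a <- random_dna(sample(1:8, 1))
        b <- random_dna(sample(1:8, 1))
        expect_equal(pairwise_align(a, b)$score, brute_global_score(a, b),
                     info = paste(a, b))
    }
})

test_that("local alignment of disjoint-alphabet strings is empty", {
    loc <- pairwise_align("AAAA", "CCCC", mode = "local")
    expect_equal(loc$score, 0)
    expect_equal(loc$columns, 0)
})

test_that("progressive alignment reconstructs inputs and handles bases cases", {
    one <- progressive_align(c(s1 = "ACGTT"))
    expect_equal(one$columns, 5)
    expect_identical(one$rows, "ACGTT")

    same <- progressive_align(c(a = "ACGTACGT", b = "ACGTACGT",
                                c = "ACGTACGT"))
    expect_equal(same$columns, 8)
    expect_false(any(grepl("-", same$rows, fixed = TRUE)))

    two <- progressive_align(c(a = "ACGT", b = "ACT"))
    expect_equal(two$columns, 4)
    expect_equal(sum(strsplit(two$rows[2], "")[[1]] == "-"), 1)

    # gap-free reconstruction on random groups
    set.seed(23)
    for (rep in 1:5) {
        base <- random_dna(60)
        seqs <- vapply(1:6, function(i) mutate_dna(base, sample(0:6, 1)),
                       character(1))
        names(seqs) <- sprintf("m%d", 1:6)
        aln <- progressive_align(seqs)
        expect_identical(gsub("-", "", aln$rows, fixed = TRUE),
                         unname(seqs))
        expect_identical(aln$ids, names(seqs))
    }
})

test_that("subgroup clustering links at 98% identity with coverage", {
    same <- cluster_subgroups(make_group("g", rep("ACGTACGTACGT", 4)))
    expect_length(same$subgroups, 1)

    # two tight clusters 5% apart link within, not across
    set.seed(31)
    a <- random_dna(300)
    b <- mutate_dna(a, 15)              # 5% divergent
    seqs <- c(vapply(1:3, function(i) mutate_dna(a, 2), character(1)),
              vapply(1:3, function(i) mutate_dna(b, 2), character(1)))
    cl <- cluster_subgroups(make_group("g", seqs))
    expect_length(cl$subgroups, 2)
    expect_identical(cl$membership, rep(1:2, each = 3))

    # mutually dissimilar sequences stay singletons
    far <- vapply(1:4, function(i) random_dna(200), character(1))
    expect_length(cluster_subgroups(make_group("g", far))$subgroups, 4)
})

test_that("alignment merging preserves column order and reconstruction", {
    a1 <- new_alignment("x", "ACGT")
    expect_identical(merge_alignments(list(a1)), a1)

    # merging two single-row alignments reduces to pairwise alignment
    a2 <- new_alignment("y", "ACT")
    m <- merge_alignments(list(a1, a2))
    pw <- pairwise_align("ACGT", "ACT")
    expect_identical(m$rows, c(pw$a_aln, pw$b_aln))

    expect_error(merge_alignments(list(a1, new_alignment("x", "AAAA"))),
                 "duplicate")

    set.seed(41)
    base <- random_dna(80)
    g1 <- vapply(1:3, function(i) mutate_dna(base, 2), character(1))
    g2 <- vapply(1:3, function(i) mutate_dna(base, 3), character(1))
    A <- progressive_align(structure(g1, names = paste0("a", 1:3)))
    B <- progressive_align(structure(g2, names = paste0("b", 1:3)))
    M <- merge_alignments(list(A, B))
    expect_gte(M$columns, max(A$columns, B$columns))
    expect_identical(gsub("-", "", M$rows, fixed = TRUE),
                     unname(c(g1, g2)))
    # column order of each input is preserved: the non-gap positions of a
    # gap-augmented row appear in their original relative order, so
    # removing gap columns inserted by the merge must recover each input
    # row's character sequence
    for (i in 1:3) {
        orig <- strsplit(A$rows[i], "")[[1]]
        merged <- strsplit(M$rows[i], "")[[1]]
        expect_identical(merged[merged != "-"], orig[orig != "-"])
    }
})

test_that("align_group switches to split-and-merge for large groups", {
    set.seed(53)
    centers <- vapply(1:3, function(i) random_dna(120), character(1))
    seqs <- unlist(lapply(1:3, function(c)
        vapply(1:50, function(i) mutate_dna(centers[c], 1), character(1))))
    names(seqs) <- sprintf("s%03d", seq_along(seqs))
    aln <- align_group(seqs, large_group_threshold = 100)
    expect_identical(gsub("-", "", aln$rows, fixed = TRUE), unname(seqs))
    expect_identical(aln$ids, names(seqs))

    # a small group takes the single-pass route and gives the same object
    small <- seqs[1:5]
    expect_identical(align_group(small, large_group_threshold = 100),
                     progressive_align(small))
})

test_that("alignment distances match a brute-force column count", {
    aln <- new_alignment(c("a", "b"), c("ACGT", "ACGA"))
    D <- distance_matrix(aln)
    expect_equal(D["a", "b"], 0.25)
    expect_equal(diag(D), c(a = 0, b = 0))

    ident <- distance_matrix(new_alignment(c("a", "b"), c("AC-T", "AC-T")))
    expect_equal(ident[1, 2], 0)

    disjoint <- distance_matrix(new_alignment(c("a", "b"), c("AC--", "--GT")))
    expect_equal(disjoint[1, 2], 1)

    set.seed(61)
    for (rep in 1:10) {
        rows <- vapply(1:3, function(i)
            paste(sample(c("A", "C", "G", "T", "-"), 30, replace = TRUE,
                         prob = c(.22, .22, .22, .22, .12)),
                  collapse = ""), character(1))
        rows <- vapply(rows, function(r)     # keep rows non-empty
            if (grepl("^[-]+$", r)) sub("-", "A", r) else r, character(1))
        aln <- new_alignment(c("a", "b", "c"), unname(rows))
        D <- distance_matrix(aln)
        M <- vapply(rows, function(r) strsplit(r, "")[[1]],
                    character(30))
        for (i in 1:2) for (j in (i + 1):3) {
            sh <- M[, i] != "-" & M[, j] != "-"
            exp_d <- if (!any(sh)) 1 else 1 - sum(M[sh, i] == M[sh, j]) / sum(sh)
            expect_equal(D[i, j], exp_d)
            expect_equal(D[j, i], exp_d)
        }
    }
})
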