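# Independent oracles and small generators used across the suite.
# These deliberately avoid the package's own code paths (except trivial
# constructors), so that implementation and check stay independent.

random_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, n_sub) {
    chars <- strsplit(seq, "")[[1]]
    pos <- sample(length(chars), n_sub)
    for (p in pos)
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    paste(chars, collapse = "")
}

make_group <- function(taxon, seqs, kingdom = "prokaryote") {
    taxon_group(taxon, data.frame(
        id = sprintf("%s_%02d", taxon, seq_along(seqs)),
        sequence = seqs, kingdom = kingdom, taxon = taxon,
        reoriented = FALSE, stringsAsFactors = FALSE))
}

# plain-ACGT reverse complement, written independently of the package
rc_plain <- function(seq) {
    vapply(strsplit(chartr("ACGT", "TGCA", seq), ""),
           function(x) paste(rev(x), collapse = ""), character(1))
}

# brute-force global alignment score by plain recursion (strings <= ~8)
brute_global_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
    memo <- new.env(hash = TRUE)
    go <- function(i, j) {
        key <- paste(i, j)
        if (!is.null(memo[[key]])) return(memo[[key]])
        res <- if (i == 0 && j == 0) 0
        else if (i == 0) j * gap
        else if (j == 0) i * gap
        else {
            s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
            max(go(i - 1, j - 1) + s, go(i - 1, j) + gap, go(i, j - 1) + gap)
        }
        memo[[key]] <- res
        res
    }
    go(nchar(a), nchar(b))
}

# brute-force every-window Hamming scan over both strands of every
# non-target database sequence; positions in forward-strand coordinates
oracle_cross_hyb <- function(expansion, groups, target_taxon, threshold) {
    l <- nchar(expansion)
    pc <- strsplit(expansion, "")[[1]]
    k <- floor(l * (1 - threshold) + 1e-9)
    out <- list()
    for (g in groups) {
        if (!is.na(target_taxon) && g$taxon == target_taxon) next
        for (r in seq_len(nrow(g$members))) {
            sq <- g$members$sequence[r]
            for (strand in c("+", "-")) {
                text <- if (strand == "+") sq else rc_plain(sq)
                tc <- strsplit(text, "")[[1]]
                L <- length(tc)
                if (L < l) next
                for (st in seq_len(L - l + 1)) {
                    nm <- sum(tc[st:(st + l - 1)] != pc)
                    if (nm <= k)
                        out[[length(out) + 1]] <- data.frame(
                            subject_id = g$members$id[r], strand = strand,
                            position = if (strand == "-")
                                L - (st + l - 1) + 1 else st,
                            n_mismatches = nm, stringsAsFactors = FALSE)
                }
            }
        }
    }
    if (length(out) == 0)
        return(data.frame(subject_id = character(0), strand = character(0),
                          position = integer(0), n_mismatches = integer(0),
                          stringsAsFactors = FALSE))
    df <- do.call(rbind, out)
    df <- df[order(df$subject_id, df$strand, df$position, method = "radix"), ]
    rownames(df) <- NULL
    df
}

hit_key_cols <- c("subject_id", "strand", "position", "n_mismatches")
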