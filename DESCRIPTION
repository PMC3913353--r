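Package: degenprobe
Title: Degenerate Oligonucleotide Probe Design for Phylogenetic
    Microarrays from Curated SSU rRNA Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Designs known and explorative oligonucleotide probes for
    phylogenetic microarrays targeting small subunit rRNA genes.  Builds a
    curated, genus-level sequence database (quality filtering, orientation
    correction, dereplication at 100% identity, homogeneity screening),
    aligns each taxonomic group (with a profile-merging strategy for large
    groups), derives an IUPAC degenerate consensus, enumerates candidate
    degenerate probes by sliding window, screens every probe expansion for
    cross-hybridization against the reference database by exhaustive
    seed-and-extend search, and balances the screening workload across
    parallel jobs with a degeneracy-weighted worst-fit partitioner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
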