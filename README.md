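# degenprobe

Design of known and **explorative** oligonucleotide probes for
phylogenetic microarrays (POAs) targeting small subunit rRNA genes, with
degeneracy-weighted load balancing for parallel specificity screening.

## The problem

Phylogenetic oligonucleotide arrays profile microbial communities by
hybridizing environmental SSU rRNA (16S/18S) amplicons against
taxon-specific probes. Designing those probes at the genus level faces
three obstacles:

* public sequence collections contain truncated, low-quality,
  mis-oriented and mis-annotated entries, which corrupt both the probe
  templates and the specificity reference;
* probes designed only from known sequences cannot detect the huge
  undiscovered fraction of microbial diversity;
* screening every candidate against a full reference database is
  computationally heavy and must be split across many jobs without
  biasing the result.

`degenprobe` addresses all three. Each curated genus group is aligned
and condensed into an **IUPAC degenerate consensus**: at every alignment
column with *m* rows and *U* unknown characters (anything outside
A/C/G/T), if *U* < *m*/2 the column's observed bases are encoded as a
single IUPAC symbol (and the unknowns repaired to it), otherwise the
consensus gets a gap. A window of length *l* (default 25) slides along
the consensus; every gap-free window whose **degeneracy**

> deg(s) = prod_i |base_set(s_i)|

does not exceed a cap (default 2000) is a candidate degenerate probe.
Its expansions are the plain-ACGT sequences it represents: expansions
observed verbatim in a group member are *known* probes, the remaining
recombinations are *explorative* probes able to capture relatives not
yet sequenced. Every expansion is screened against the reference
database: any ungapped window on either strand of a non-target sequence
with identity ≥ *S* (default 0.88, inclusive) is a cross-hybridization,
and a degenerate probe is rejected when its expansions accumulate more
than a cap (default 100) of them. The screen is an exhaustive
seed-and-extend search whose seed width ⌊*l*/(k+1)⌋ (capped at 7, k =
allowed mismatches) makes it provably equivalent to a brute-force
Hamming scan of every window.

For parallel execution the candidate probes are split into *N* jobs by a
**worst-fit** heuristic on their weights (weight = degeneracy): probes
are sorted by descending weight and each is placed in the currently
lightest job. The per-job loads then differ by at most one probe weight,
so all jobs carry almost the same screening effort — in contrast to
splitting the consensus into *N* equal parts, which can leave jobs
several-fold apart. Job loads are summarized by their mean and sample
(n−1) standard deviation.

## Worked example

```r
library(degenprobe)

# synthetic genus-like fixture: 3 groups of 6 sequences plus one planted
# duplicate, short entry, reversed entry and divergent outlier per group
fx <- generate_fixture(fixture_spec(n_groups = 3, sequences_per_group = 6,
                                    template_length = 360, seed = 11),
                       "fixture")

cfg <- run_config(fasta = fx$paths$fasta, taxonomy = fx$paths$taxonomy,
                  reference = fx$paths$reference, out_dir = "run",
                  min_length = 300, job_count = 4, seed = 5)
res <- design_pipeline(cfg)
#> input: 27 record(s)
#> curate: 3 group(s), 18 of 27 record(s) kept
#> design: 1008 candidate probe(s), total degeneracy 10386
#> partition: 4 job(s), mean load 2596.50, load sd 0.5774
#> screen: 10386 expansion row(s), 3509 cross-hybridization(s), 1007/1008 probe(s) accepted
```

The log reads as follows: of 27 input records, curation kept 18 (one
duplicate, one too-short entry and one outlier removed per group; one
member per group re-oriented). The three group consensus sequences
yielded 1008 gap-free candidate probe windows whose degeneracies sum to
10386; worst-fit split them into four jobs of 2596–2597 (sample sd
0.577, the theoretical floor when the total is not divisible by 4).
Screening all 10386 expansions found 3509 cross-hybridizations between
groups, rejecting the single probe that exceeded the cap. `run/`
contains every intermediate: curated groups, alignments, consensus
FASTA, the probe table, per-job subfiles, and the merged `results.tsv` /
`hits.tsv` — identical whatever `job_count` was.

A thin command-line front end covering the same stages is installed at
`inst/exec/probedesign`.

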