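---
title: "Methods: degenerate probe design, specificity screening and load balancing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: degenerate probe design, specificity screening and load balancing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degenprobe)
```

## Overview

`degenprobe` designs oligonucleotide probes for phylogenetic
microarrays targeting SSU rRNA genes. The pipeline has five stages,
each exposed as ordinary functions and run end-to-end by
`design_pipeline()`:

1. **Curation** (`build_database()`): quality-filter sequences, group
   them at a taxonomic rank, correct strand orientation, remove
   redundant entries, and screen each group for homogeneity.
2. **Alignment** (`align_group()`): progressive multiple alignment per
   group, with a split-and-merge strategy for large groups.
3. **Consensus and enumeration** (`build_consensus()`,
   `enumerate_probes()`): condense the alignment into an IUPAC
   degenerate consensus and slide a probe-length window along it.
4. **Specificity** (`evaluate_probe()`, `screen_probes()`): expand each
   degenerate probe, label expansions known/explorative, and count
   cross-hybridizations against the reference database.
5. **Partitioned execution** (`worst_fit_partition()`,
   `run_jobs_local()`): balance the screening workload across N jobs by
   probe degeneracy and merge results deterministically.

This vignette records the model assumptions, parameter choices,
numerical conventions and limitations; design choices that were
genuinely open are flagged as such.

## Curation model

A record passes the quality filter when, in this order: its length is
strictly greater than `min_length` (default 1200 bases) and strictly
below the kingdom maximum (1600 for prokaryotic 16S, 1800 for fungal
18S — full-length gene scale, excluding concatenates and genomic
fragments); it carries a taxon label; its fraction of unknown
characters (anything outside A/C/G/T) is strictly below 1%; and no run
of unknowns exceeds 5 bases (inclusive). The strict/inclusive reading of
each bound follows the wording of the criteria the defaults come from;
the fixed rule order only determines which reason is *reported* when
several fail, so reports are deterministic.

**Orientation.** Each kept sequence is locally aligned against a trusted
same-kingdom reference (a required input — there is no sensible
default); if its reverse complement scores strictly higher, the record
is flipped and flagged. Equal scores keep the record as given. The
operation is idempotent.

**Dereplication.** Redundancy at 100% identity with coverage required on
only one sequence of a pair reduces to exact identity or substring
containment, so no alignment is needed: a member is removed when it is
a substring (or equal copy) of another; among equal copies the earlier
input survives, and longer sequences are considered first so a
containment chain keeps only its maximal element.

**Homogeneity.** The group is aligned, pairwise distances are computed
(one minus column identity over shared gap-free columns), and each
sequence is embedded as its row of the distance matrix. K-means with
K = 2 splits the embedding; the larger cluster is retained. Open
choices resolved here:

* *Initialization*: the two members at maximal pairwise distance seed
  the centers (first maximal pair in column-major order), then Lloyd
  iterations (`stats::kmeans`, ≤ 100 iterations) — fully deterministic,
  no random restarts.
* *No-split margin*: if the two centroids are separated by less than
  0.10 RMS per coordinate, the group is declared homogeneous and kept
  whole. The RMS (Euclidean distance divided by √n) is used because it
  lives on the sequence-distance scale, so 0.10 means "the two
  sub-clusters differ by about 10% sequence distance" — comfortably
  above within-genus scatter and below mis-annotation distances.
* *Ties*: equal cluster sizes keep the cluster containing the earlier
  input sequence. A group of identical sequences, or one producing an
  empty cluster, is kept whole. At most half the group can ever be
  removed.

## Alignment engine

All alignment operations share one dynamic-programming core (compiled,
linear gap penalties; match +1, mismatch −1, gap −2 by default). Two
profile columns score as the expected pairwise score
`match·P(same base) + mismatch·P(different base)` with IUPAC codes
spreading 1/|set| over their bases and gaps contributing nothing; a
column aligned to a gap costs `gap` scaled by the column occupancy.
This reduces exactly to the plain scheme on ungapped sequences.

Determinism is enforced throughout: ties in the recurrence prefer
diagonal, then consuming the first profile, then the second; the local
(Smith–Waterman) variant reports the first best cell in row-major
order; guide trees come from single-linkage `hclust` on global-alignment
identity with stable input-order processing. Progressive alignment
merges leaves and intermediate alignments by profile–profile alignment,
which only ever inserts whole gap columns — hence two invariants hold by
construction and are property-tested: stripping gaps from any row
reproduces its input byte-identically, and merging never reorders the
columns of an input alignment.

Groups larger than `large_group_threshold` (default 100 — a pragmatic
cutoff, configurable; "large" is not defined by the method) are first
clustered into subgroups of highly similar sequences (single linkage;
linked when global identity ≥ 98% over ≥ 98% of the shorter sequence's
length), each subgroup aligned independently, and the subgroup
alignments merged. Identity is matches over alignment columns; coverage
is the fraction of the shorter sequence aligned residue-to-residue.

The built-in aligner does not attempt to reproduce any external
aligner's output column-for-column; alignments from an external tool
can be read with `read_alignment()` and fed to every downstream stage.

## Consensus rule and probe enumeration

For each column with *m* rows, let *U* be the number of unknown
characters. If *U* < *m*/2 (strictly; exactly half gets a gap), the
consensus symbol is the IUPAC code of the set of observed specific
bases, and the unknowns in that column are *repaired* to this code in
the corrected alignment — treating isolated N's and gaps as likely
sequencing artifacts rather than evidence. Otherwise the consensus gets
a gap and the column is untouched. "Unknown" defaults to any non-ACGT
character: other ambiguity codes carry the same uncertainty as N (a
`strict` mode restricting unknowns to {N, −}, with ambiguity codes
contributing their base sets, is available). The rule is idempotent on
its corrected alignment; a column with *U* < *m*/2 always contains at
least one specific base, so the code is always defined.

Probe enumeration slides a window of `probe_length` (default 25 — the
usual compromise between sensitivity and single-mismatch
discriminability on POAs) along the consensus. Windows containing a gap
or exceeding `max_degeneracy` (default 2000, which also caps expansion
memory) are discarded. Start positions are 1-based *including* gap
columns, so positions remain stable identifiers across parameter
changes. Probe weight equals degeneracy — the simplest weight consistent
with per-job "degeneracy" being the balanced quantity; it is exactly
the number of expansions a job must screen for that probe.

An expansion is **known** if it occurs verbatim (forward strand) in a
group member, else **explorative**. Explorative status is judged
against the probe's own group only; the specificity screen against the
full database is a separate question answered by the next stage.

## Specificity screen

A cross-hybridization is any ungapped window, on either strand of a
non-target database sequence, with identity ≥ `specificity_threshold`
(default 0.88, inclusive: 22/25 counts). The hit model is mismatch-only
(no gaps): 25-mer probe/target duplexes are conventionally scored by
mismatches, and the reported per-hit detail is the list of 1-based
mismatch offsets. Positions are reported in forward-strand coordinates.

The search tiles the probe into k+1 disjoint seeds of width
min(7, ⌊l/(k+1)⌋), where k = ⌊l(1−S)⌋ is the allowed mismatch count;
by pigeonhole every window with ≤ k mismatches matches at least one
seed exactly, so seed-and-extend finds *exactly* the brute-force hit
set (asserted against an independent all-window Hamming oracle on
randomized databases). A prebuilt `build_screen_index()` makes repeated
screens against the same database cheap.

Counting unit: one (expansion, subject sequence, position, strand)
tuple. Totals are summed over all expansions of a degenerate probe
before comparison with `max_cross_hyb` (default 100) — the strictest
consistent reading; per-expansion counts are also reported. Hits inside
the target taxon are excluded from the count but can be kept for
auditing.

## Load balancing and execution

Probes are sorted by descending weight (ties keep input order) and each
is assigned to the job with the greatest remaining capacity relative to
the mean load — with all bins equivalent, that is the currently lightest
job, ties to the lowest index. Every probe must be placed, so no
overflow rejection exists; the classic greedy bound
`max(load) − min(load) ≤ max single weight` holds and is
property-tested. With unit weights and N dividing the count within one,
the result is perfectly balanced: load sd 0 on exact division, √(1/N)
otherwise (0.5 at N = 4) — the theoretical floor of any partitioner.
`load_stats()` uses the sample (n−1) standard deviation, the convention
under which the published four-job loads reproduce their printed
dispersions; a single job has sd 0 by definition.

Execution is local: each job's probe table goes to a worker function
(serial by default, fork-based pool optional), a failed job is retried
up to `max_retries` times (so at most `max_retries + 1` attempts), and
a job exhausting its retries aborts the run with a manifest of job
states and the partial results. Merged results are canonically sorted
(taxon, start, probe sequence, expansion, then hit coordinates) before
writing. The natural alternative — concatenating in job order — would
make the output depend on N, since worst-fit redistributes probes
across jobs; canonical sorting makes single-job and multi-job runs
byte-identical, which the suite asserts. Parallelization must not
change the science.

## Synthetic fixtures

`generate_fixture()` emulates a genus-level SSU collection: a random
ancestor, per-group templates mutated from it at `divergence` (default
0.10, typical between-genus 16S distance), members mutated from their
template at `substitution_rate` (default 0.02, within-genus scatter)
with sparse N injection (default 0.001), plus planted defects with
known ground truth — exact duplicates, entries truncated to 70% of the
template (falling below the curation minimum), reverse-complemented
members, and outliers mutated at 0.35 (emulating mis-annotated
entries). A distinct 25-base tag (pairwise Hamming ≥ 10) is embedded in
each group template, giving each group probe windows with no
counterpart elsewhere. Everything is a pure function of the seed;
identical specs give byte-identical files.

What the generator does **not** emulate: real rRNA covariation and
conserved/variable region structure, indel processes (members differ by
substitutions only, so true alignments are trivial), chimeras, and
database-scale taxon imbalance. Tests passing on fixtures therefore
validate the machinery — filtering rules, orientation, dereplication,
outlier removal, consensus algebra, screening exactness, balance,
determinism — not probe quality on real data, which additionally
depends on alignment quality for indel-rich groups and on the
completeness of the reference database.

## Problem sizes and numerical conventions

The test and acceptance workloads are sized for a laptop-class single
core: 10-group fixtures at 1300 bases for the curation audit, 3-group
fixtures at 360 bases (with `min_length` 300) for end-to-end runs, 100
randomized databases of ~2.4 kb for the screening oracle, 1000
randomized weight sets for the balance property. Scale-up is linear in
groups and jobs; the screening index makes repeated probe evaluation
sublinear in database size in practice.

Numerical conventions worth stating: degeneracies are exact integers
held in doubles (a 25-mer's maximum, 4^25, is within exact double
range); load statistics agree with a direct two-pass computation to
1e−9 relative error; all string sorts use radix order (locale
independent); every stochastic component (fixtures only — K-means is
deterministically initialized) flows from a single seed.

## Known limitations

* The built-in aligner uses linear gap penalties and no iterative
  refinement; heavily gapped groups are better served through the
  external-alignment route.
* The homogeneity screen removes at most one cluster (K = 2); a group
  contaminated by two distinct foreign clades needs two passes.
* The specificity model ignores thermodynamics (Tm, ΔG, position
  effects); identity-fraction screening is the standard proxy at this
  probe length but not a hybridization model.
* Explorative expansions recombine only variation observed within the
  group; diversity absent from the curated members remains invisible.
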