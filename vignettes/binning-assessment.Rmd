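---
title: "Assessing metagenome genome binnings: model, metrics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing metagenome genome binnings: model, metrics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binbench)
```

## The evaluation model

A genome binner partitions the sequences of a metagenome — reads or
assembled contigs — into bins, each meant to collect the sequences of one
community genome. On a benchmark dataset the true partition is known: the
gold standard maps every sequence to its source genome and records its
length in base pairs. `binbench` compares the two partitions.

The unit of assignment is the whole sequence; sub-sequence (chimeric
contig) resolution is out of scope, matching the input model of the
benchmark formats it reads. Base pairs are the default currency for every
metric, because a 500 kb contig misplaced matters more than a 1 kb one;
sequence counts are kept alongside for the per-sequence adjusted Rand
index.

Evaluation proceeds in three stages:

1. **Contingency** (`build_contingency()`): a bins-by-genomes table of
   overlaps in bp and in sequence counts. Query sequences absent from the
   gold standard are excluded from evaluation entirely — the metrics are
   defined only over gold-standard content — with a counted warning so
   data loss is never silent. Gold-standard base pairs in no bin form the
   unassigned tally U.
2. **Bin-to-genome mapping** (`map_bins_majority()`,
   `map_bins_fraction()`): predicted bins carry no label, so each bin is
   mapped either to the genome contributing most base pairs to it
   (majority overlap, the default) or to the genome with the largest
   *fraction* of its own base pairs in the bin. The first mapping names
   the genome that best represents the bin; the second names the bin that
   best represents a genome. A genome can map to several bins or to none.
3. **Metrics** (`per_bin_metrics()`, `evaluate_all()` and friends),
   described next.

## Metrics and their conventions

Per bin: purity `TP/(TP+FP)`, completeness `TP/(TP+FN)`, contamination
`1 - purity` (an exact complement, asserted in tests to machine
precision). Macro averages treat every bin equally; the average
completeness divides by bins *plus* unmapped genomes, so abandoning a
genome costs completeness even though the genome has no bin record, and
its purity is simply undefined. The bp-weighted counterparts and the
accuracy `sum(TP) / (U + assigned bp)` weight by size; the bp-weighted
family and accuracy always use the majority-overlap maxima, even when the
fraction criterion was selected for per-bin reporting, because they
answer "how much of the data sits in the right bin", a question about
bins, not genomes.

The adjusted Rand index is computed from the contingency table's choose-2
sums, over the assigned portion only: binners legitimately leave data
unassigned, and counting the unassigned portion would let "assign
nothing" look like clustering skill. An ARI must therefore always be read
next to the fraction of data assigned, and the report pairs them in one
plot. Choose-2 terms are formed from exact integer tallies, and the
expected-index product is evaluated as `(S_rows/C(m,2)) * S_cols` so that
intermediate magnitudes stay inside the exactly-representable double
range even for multi-gigabase samples.

Degenerate ARI inputs (fewer than two assigned items, or a zero
denominator as for a single bin over a single genome) return 1 when the
two partitions of the assigned portion are identical and 0 otherwise,
preserving the perfect-binning invariant. An empty evaluable binning is
an error at the contingency stage; at the metric layer the conventions
are: average purity reported as 0 with a `defined = FALSE` flag, average
completeness 0.

### Tunable parameters

- **`alpha` (percentile, default 99):** the truncated average purity
  removes the smallest bins totalling `100 - alpha` percent of the
  assigned base pairs before averaging. Tiny bins are of little practical
  interest but, being typically impure, they distort an unweighted mean;
  the 99th percentile removes the bottom 1% of assigned data.
  Implementation: bins sorted by size descending are retained while the
  data before them is below the alpha fraction, so the bin straddling the
  threshold is kept, as is any dropped bin of exactly the size of the
  last retained one. `alpha = 100` is the exact identity.
- **Recovery thresholds (defaults: contamination < 5% and < 10%;
  completeness > 50%, 70%, 90%):** strict inequalities on both sides. A
  genome counts once per threshold pair however many of its bins qualify.
- **Mapping criterion (default majority overlap):** ties under either
  criterion break to the larger genome, then the byte-order smaller id —
  mirroring the fully-contained-genomes rule of the fraction criterion
  and keeping every result deterministic.
- **Standard errors:** the purity standard error is the sample standard
  deviation over the truncated bin set (the set whose mean is plotted)
  divided by the square root of its size; the completeness standard error
  is taken over bin completenesses plus one zero per unmapped genome.
  Single-element sets report 0.

## Report layout

The heat map shows the full contingency table with bins sorted by true
positives descending (ties: larger bin, then label) and genome columns
following the mapped genome of each bin in first-occurrence order,
unmapped genomes appended by descending size; a terminal row carries the
unassigned base pairs per genome. Row sums therefore equal bin sizes,
column sums equal genome sizes, and the grand total equals the
gold-standard base pairs in scope — an invariant the tests assert on
random instances. Row scatter reads as underbinning (genomes fused into
one bin), column scatter as overbinning (one genome split over many
bins). Cell values are raw base pairs; the log scaling is applied only at
render time so the matrix itself stays exact.

Every figure's numeric series is also written as a TSV next to the image,
so rendering is verifiable numerically, and the whole run is
deterministic: tables are sorted in byte order, numbers rendered at 6
significant digits, and two runs on the same input are byte-identical —
also asserted in tests.

## The synthetic benchmark generator

`generate_gold_standard()` draws a community with per-genome contig
counts and contig lengths uniform over configurable ranges (defaults:
5–20 contigs of 1–100 kb), giving genome sizes that vary severalfold
across the community. `perturb_binning()` starts from the perfect
one-bin-per-genome solution and corrupts it in a fixed order — merge bin
pairs, split bins, misassign sequences, unassign sequences — chosen so
that expected-metric reasoning stays tractable: a single merge, for
instance, provably leaves exactly one impure bin. Unassignment and
misassignment are per-sequence Bernoulli draws, so realized fractions
fluctuate binomially around the rate, as sequence-level dropout does in
real binners; reusing one seed across rates makes the dropped sets nested
and the metric response provably monotone. All randomness flows from one
seed per call, with the caller's RNG state restored afterwards.

What the generator does *not* emulate: read-level coverage and abundance
structure, sequencing error, strain-level mosaicism, or chimeric contigs.
Passing tests on synthetic data therefore demonstrates the correctness of
the bookkeeping and the metric arithmetic under controlled error modes —
not that any binner performs well on real communities, nor that the
degradation rates resemble a particular instrument or assembler.

The worked five-contig example (`fixture_f1()`) is small enough that
every metric is a short hand calculation; the test suite pins the whole
vector at a relative tolerance of 1e-9, and the adjusted Rand index is
cross-checked against a brute-force pair-enumeration oracle on hundreds
of seeded random instances. Problem sizes throughout the suite (up to 50
genomes, 2,000 sequences) keep the full run in well under a minute while
still exercising every code path; the binomial calibration check uses
2,000 sequences so the 99% interval around the unassignment rate is
narrow enough to be informative.

## Known limitations

- One gold standard per run; multi-sample time series are evaluated
  sample by sample.
- Taxonomic (TAXID-based) binning evaluation is out of scope; TAXID
  columns are carried through as metadata only.
- A sequence may sit in only one bin and one genome; overlapping or
  soft assignments are rejected at parse time (optionally keeping the
  first assignment).
- Marker-gene quality estimation on real (gold-standard-free) samples is
  the role of complementary tools and is deliberately not replicated.
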