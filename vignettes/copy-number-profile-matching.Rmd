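---
title: "Matching copy number profiles: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching copy number profiles: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnmatch)
```

# The problem

Cancer cell lines are routinely chosen as experimental models for tumours,
and a poor model choice propagates into every downstream result. Genome-wide
absolute copy number is a compact, caller-agnostic readout of a sample's
chromosomal-instability history, and two cultures of the same cell line
should have nearly identical profiles. `cnmatch` answers three practical
questions: *is this profile the cell line it claims to be* (quality
control), *how different are two cultures* (percentage genome difference),
and *which reference cell line best models this tumour profile* (ranked
matching, by profile or by mutational-process signature exposures).

# From segment tables to comparable vectors

The input is the standard output of an absolute copy number caller such as
ASCAT: a segment table of `(chromosome, start, end, copy number)` rows per
sample, 1-based inclusive coordinates. Profiles from different samples have
different breakpoints, so segment tables are not directly comparable.
`segments_to_bins()` rasterizes each profile onto a fixed grid of
equal-width bins (`make_bin_grid()`, default 500 kb on hg19 autosomes + X),
turning every profile into a fixed-length numeric vector.

The bin value is the **coverage-length-weighted mean** copy number of the
segments overlapping the bin. This rule is deterministic, robust to
boundary jitter, and conserves copy mass: the sum of bin value times
covered length equals the sum of segment copy number times segment length
(the acceptance suite checks this to floating-point precision). A bin with
no covering segment is flagged missing, and every downstream comparison
uses only bins that are non-missing in *both* profiles — no imputation, no
bias from uncovered telomeres or assay gaps.

Coordinates are converted internally to 0-based half-open intervals so
that adjacent segments and adjacent bins abut without gap arithmetic.
Chromosome Y is excluded by default (cell-line Y coverage is unreliable);
any genome can be supplied as a named length vector or a UCSC
`chrom.sizes` file. Bin sizes below 30 kb trigger a warning because
SNP6-derived reference profiles do not support finer resolution.

# Boundary smoothing

Even sister cultures of one cell line disagree by a bin or two on where a
copy number transition falls, which inflates every distance metric.
`align_boundaries()` removes this artefact before scoring: when one
profile changes value at bin *i* and the other changes within ±`window`
bins (default 1), the later transition is shifted to the earlier position
by re-assigning the intervening bins to the post-transition value.

The concrete snapping rule is this package's own design. It was chosen as
the simplest procedure that is **symmetric** in the two profiles (pairs of
near-coincident transitions are matched closest-first with deterministic
tie-breaks, and the "later moves to earlier" rule does not care which
profile is which) and **idempotent** (snapping runs to a fixed point; a
second application changes nothing). One guard is required by
level-preservation: a shift that would consume an intervening copy number
run — a run shorter than the window sitting between the two boundaries —
is skipped, so smoothing never creates or destroys a copy number level,
it only moves boundaries. Transitions never move across chromosome ends,
and missing bins break the runs they interrupt.

# Four metrics and what they measure

For profiles $x, y$ over the $n$ pairwise-complete bins:

* Pearson correlation $r = \mathrm{cor}(x, y)$ — higher is better;
* Manhattan distance $\sum_i |x_i - y_i|$ — lower is better;
* Euclidean distance $\sqrt{\sum_i (x_i - y_i)^2}$ — lower is better;
* cosine similarity $\sum_i x_i y_i / (\lVert x\rVert\,\lVert y\rVert)$ —
  higher is better, in $[0,1]$ for non-negative profiles.

The scientifically important split is **ploidy awareness**. Pearson and
cosine are normalized: for non-constant $x$, $r(x, 2x + 1) = 1$ and
$\cos(x, 2x) = 1$, so a whole-genome-doubled culture (or a caller that
fitted double the ploidy) still matches perfectly. Manhattan and Euclidean
are absolute: $\mathrm{man}(x, 2x) = \sum_i |x_i| > 0$, so they punish
ploidy differences — which is what you want when the question is "is this
*exactly* the same genome", and what you do not want when callers disagree
about genome doubling. The simulated sister-culture benchmark
(`benchmark_recovery()` with `ploidy_shift = 2` and diploid decoys)
reproduces this failure mode qualitatively: normalized metrics keep
recovering the true partner while the absolute distances are pulled to
decoys of closer ploidy.

Degenerate inputs (constant profile under Pearson, all-zero profile under
cosine) raise errors instead of propagating `NaN`, because a silent `NaN`
would corrupt a ranking.

**Percentage genome difference** is the fraction of compared bins whose
values differ by more than a tolerance, ×100. The tolerance default is
0.5 copies: two bins count as different when they would round to
different integer copy states. It is configurable (`tolerance`) because
no canonical threshold exists for non-integer segment means.

# Ranked matching and empirical significance

`rank_matches()` scores a query against every reference (smoothing
applied pairwise, window 1 by default), sorts best-first under the chosen
metric, and breaks score ties lexicographically by reference id so that
rankings are reproducible. Each score's significance is assessed against
an **empirical null**: the query's scores against all *other* references,
with the add-one estimator

$$p = \frac{1 + \#\{\text{null scores at least as extreme}\}}{1 + n_{\text{null}}}.$$

This is self-contained and assumption-free; it asks "is this match better
than this query's typical match in this collection", which is the
operative question when screening a database. Users who need a different
null (e.g. per-reference permutation of bins) can feed any score vector
to `empirical_pvalue()` directly. Under exchangeability the estimator is
uniform on a discrete grid and can never return 0; `calibrate_pvalues()`
verifies uniformity by simulation (Kolmogorov–Smirnov statistic ≈ 0.05 at
1000 replicates with 24 references, comfortably below the 0.1 bar the
test suite enforces). The p-values for Pearson and Manhattan follow the
same construction as the significance calls reported for real cell-line
databases; for Euclidean and cosine the construction is identical but has
no published counterpart to compare against.

# Signature-exposure matching

Copy number signatures summarize *which mutational processes* generated a
profile rather than the profile itself; a sample's exposures form a
non-negative composition over signatures (rows sum to 1; the
seven-signature ovarian model is the expected shape, any count ≥ 2 is
accepted). Two samples are compared directly by `exposure_cosine()`, and
a cohort is structured with `cluster_exposures()` — standard k-means with
the squared-Euclidean objective on raw exposure rows, a mandatory seed
and 10 random restarts, so labels are reproducible. Cosine geometry is
offered for the pairwise comparison only, not inside k-means, keeping the
clustering a textbook objective. The cluster count `k` is a required,
explicit choice: no automatic model selection is imposed, but
`silhouette_scan()` reports mean silhouette widths over candidate `k` to
inform the choice. For visualization, `top_variable_signatures()` picks
the signatures whose centroid values vary most across clusters — the two
axes that best discriminate the groups — and `write_cluster_report()`
exports sample and centroid coordinates on them.

# The simulator: what it emulates, what it does not

`simulate_profile()` generates piecewise-constant per-chromosome profiles:
uniform breakpoints without replacement, integer copy states drawn from a
weight vector over 0..8, optional global ploidy scaling.
`perturb_profile()` derives a "sister culture": breakpoints jittered
uniformly within ±`boundary_jitter` (clamped, never invalid), a random
segment subset covering approximately `noise_fraction` of the genome
shifted by ±`noise_magnitude` copies (floored at 0), and a ploidy
multiplier. Noise is **segmental**, not per-bin white noise, because
re-culture differences are segmental in real data. The noisy-segment
selection takes a permuted prefix whose cumulative length lands closest to
the target fraction, so requested and realized coverage agree tightly.

Defaults were fixed once as the package's study conditions: 22
chromosomes × 130 Mb (human-scale), 2–12 segments per chromosome, state
weights peaked at copy 2 with a tail to 8 (near-diploid cancer genome),
ploidy scale 1. The benchmark re-enactments in the acceptance suite run
50 profiles on a 12 × 50 Mb genome at 500 kb bins (1200 bins) — large
enough that cross-sample similarity concentrates near zero, small enough
to run in seconds — and the p-value calibration uses 1000 replicates of
1 query + 24 references on a 4 × 10 Mb genome.

What the simulator does **not** emulate: focal amplifications with very
high copy numbers, wavy GC biases, subclonal (non-integer) segment means,
correlated breakpoint reuse between unrelated samples, and real tissue
structure. Passing the synthetic benchmarks therefore demonstrates the
correctness and the qualitative metric behaviour of the pipeline, not
field performance on any particular cell-line database; real-data
performance depends on the upstream caller and the reference collection
used. A real database in the same TSV format plugs in through
`read_segment_table()` + `build_reference()`.

# Numerical and degenerate-input choices

* Binning uses exact cumulative-sum interval arithmetic; a bin fully
  inside one segment reproduces that segment's value to machine
  precision (an independent GenomicRanges overlap computation is used as
  the oracle in the test suite).
* All randomized APIs (`simulate_*`, `perturb_profile`,
  `cluster_exposures`) take a mandatory seed and are deterministic given
  it; reports are byte-identical across reruns of the same configuration.
* Score ties in rankings and variance ties in signature selection break
  by id order; k-means cluster indices are arbitrary and all reported
  quantities are invariant under relabeling.
* Exposure rows are renormalized when their sum is within $10^{-3}$ of 1
  and rejected otherwise; entries must be non-negative and finite.
* `k = n` clustering is the exact degenerate fit (singletons, objective
  0); `k < 2` or `k > n` is an error.
* Pearson needs ≥ 2 pairwise-complete bins and non-zero variance on both
  sides; percentage genome difference needs ≥ 1 shared bin.

# Known limitations

* The boundary-snapping smoother is a deliberately simple stand-in for
  more elaborate multi-sample segment-harmonization procedures; it only
  aligns transitions that already lie within the window.
* The empirical null is collection-relative: p-values move when the
  reference collection changes, and a collection of near-duplicates makes
  every match look insignificant.
* Only total absolute copy number is compared; allele-specific states,
  LOH and subclonality are invisible to all four metrics.
* Matching quality can never exceed the quality of the upstream absolute
  copy number calls.
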