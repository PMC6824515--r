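---
title: "Measuring TAD variability: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring TAD variability: models, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadvar)
```

# Overview

`tadvar` measures how much topologically associating domains (TADs) vary
between Hi-C experiments. The pipeline has five stages: ingest or simulate
binned intra-chromosomal contact matrices; gate samples on coverage;
balance matrices by iterative correction; call TADs with a
gamma-parameterised dynamic program selected to a target median domain
size; and score all sample pairs with three complementary similarity
measures whose distributions are then compared across biologically
meaningful pair groups with Mann–Whitney U tests. This vignette explains
the model behind each stage, the tunable parameters, and the design
decisions taken where the methods literature leaves the details open.

# Contact matrices and the coverage gate

A `ContactMatrix` is a symmetric, non-negative `n x n` matrix of contact
counts between fixed-width genomic bins (100 kb by default) on one
chromosome. Only intra-chromosomal matrices are modelled: all three
similarity measures operate within chromosomes. Bin indexing is 0-based and
genomic intervals are half-open, following BED conventions, which removes
any off-by-one ambiguity between coordinates and bins.

A sample is considered analysable at a given resolution when at least 80%
of its bins contain more than 1000 contacts (both thresholds are
arguments). A bin's contact total is defined as its row marginal with the
diagonal counted once; the marginal is the standard notion of per-bin
coverage, and because the convention is not universal the diagonal can be
excluded with `include_diagonal = FALSE`. The contact threshold is strict
("more than"), so a marginal of exactly 1000 does not pass.

Replicate libraries of one sample are pooled by entrywise summation
(`merge_replicates`) before non-replicate comparisons, mirroring standard
practice of merging replicates for maximal depth.

# ICE balancing

Iterative correction removes multiplicative per-bin biases by factorising
`counts[i,j] = bias_i * bias_j * W[i,j]` such that the balanced matrix `W`
has equal row sums on usable rows. The implementation iterates
proportional fitting: divide by the outer product of the current row-sum
ratios and repeat. Numerical choices, none of which are standardised in the
literature:

* target: unit mean row sum over nonzero rows;
* convergence: maximum relative change of the bias vector below `tol`
  (default `1e-6`), capped at `max_iter = 200` iterations — exceeding the
  cap warns and returns the partial result flagged `converged = FALSE`;
* all-zero rows (unmappable bins) are excluded from balancing, keep bias 1,
  stay zero, and are reported in `unusable_bins`. They are also excluded
  from the equal-row-sum contract.

The exact factorisation `counts = bias bias' ∘ W` is maintained to within
floating-point error at every exit path, which the tests verify directly.

# TAD calling

A domain is a run of bins `[k, l]` whose internal contact density is high
for its length. The caller scores each candidate interval by the scaled
density

```
q_gamma(k, l) = S(k, l) / (l - k + 1)^gamma
```

where `S(k, l)` sums the strict upper triangle of the block. The resolution
parameter `gamma` (unitless, grid `0, 0.1, ..., 1` by default) controls the
preferred domain size: larger values penalise long domains. Because the
absolute scale of `q` varies with length, scores are centered by the mean
over all same-length intervals in the matrix (`q'`), so that enriched
blocks stand out as positive regardless of their length. The optimal
partition-with-gaps maximising the summed `q'` over non-overlapping
domains is found by the dynamic program

```
OPT(l) = max( OPT(l-1), max_k { OPT(k-1) + q'(k,l) : q'(k,l) > 0 } )
```

and only strictly positive-quality domains are emitted. The testthat suite
pins this objective against an exhaustive enumeration over all
non-overlapping interval subsets on small matrices, so the implemented
definition cannot drift silently.

Two practical caps keep the table small: the minimum domain length is 2
bins (a 1-bin domain has no internal contacts) and the maximum is 3 Mb
worth of bins by default; both are arguments.

**Gamma selection.** For each sample (and, in multi-chromosome use, each
chromosome) the sweep keeps the call whose median domain length is closest
to a target, 880 kb by default — a widely used expectation for the median
TAD size. Ties break toward smaller gamma; empty calls are never selected
(their median is defined as 0), and an error is raised only if every gamma
yields an empty call. The robustness machinery re-selects gamma for targets
of 500 kb, 700 kb, 880 kb and 1 Mb to check that group orderings are not
artefacts of the target choice.

# Similarity measures

## Boundary Jaccard index

Two TAD sets are compared as sets of boundary positions (domain starts and
ends, deduplicated, so a boundary shared by adjacent domains counts once):
`JI = |A ∩ B| / |A ∪ B|`. The default match is exact at the working
resolution (100-kb bins); a `tolerance_bins` argument instead counts the
intersection via a maximum bipartite matching of boundaries within the
tolerance (computed greedily, which is optimal for this convex adjacency
structure, and verified against brute-force enumeration in the tests).
Two empty sets are defined to agree vacuously (JI 1 with a warning) so
cohort pipelines do not fail on empty chromosomes.

## Local variation of information and TADsim

The variation of information between two partitions of the same window is
`VI = H(P) + H(Q) - 2 I(P,Q)` in nats. For partitions made of contiguous
blocks this reduces to `2 H(joint) - H(P) - H(Q)` where the joint partition
is induced by the union of the two breakpoint sets. Each TAD is one block
and each maximal non-TAD run is its own background block — a single global
"background" label would let two samples appear to agree merely by sharing
gaps far apart. VI is a true metric (identity, symmetry, triangle
inequality), which the suite checks on thousands of random partition
triples.

`tadsim` turns local VI into a genome-scale similarity: the fraction of the
TAD-covered genome lying in regions where the two partitions agree more
than chance would allow. The pinned construction:

1. **Segmentation.** Candidate window endpoints are the boundaries of
   either set; windows are capped at 5 Mb (`max_window_bins`). The span
   between the first and last boundary is segmented into disjoint windows
   by a dynamic program minimising total length-weighted VI, ties broken
   toward longer segments. Disjoint segments — rather than the union of
   every significant window among the thousands of overlapping candidates —
   are essential: with overlapping windows, any bin flanked by agreement on
   either side ends up inside some "significant" window, and coverage
   saturates at 1 even for substantially different partitions (and exceeds
   0.4 for completely unrelated ones, as the development experiments in the
   test suite's calibration cases reflect). With a segmentation, every
   locally disagreeing stretch must belong to some segment and drags that
   segment out of significance.
2. **Scoring.** A segment's statistic is its VI normalised by
   `log(segment length)` so segments of different sizes are comparable.
3. **Null.** Per segment length, both inputs' genome-wide boundary sets are
   independently circularly shifted and clipped to the window (`n_null`
   draws, default 1000, seeded). Circular shifting preserves each input's
   TAD-length multiset *and* its gap structure exactly while randomising
   alignment. A re-placement null that packs the length multiset into the
   window was rejected because it becomes degenerate for near-uniform
   length multisets (zero free space leaves a single possible placement),
   making even identical partitions untestable.
4. **Significance.** `p = (1 + #{null VI < observed}) / (1 + n_null)`, with
   a strict inequality so that a segment with VI = 0 beats any null draw —
   with `<=`, a null atom at zero would make perfectly identical partitions
   non-significant. Segments shorter than `min_window_bins` (default 3
   bins) or containing no boundary of either set (no internal structure,
   hence no evidence) are never called significant. Significant segments at
   level `alpha` (default 0.05) are unioned; coverage is the fraction of
   TAD-covered bins inside the union.

Under this construction identical tiling partitions score exactly 1 for any
seed, independent random TAD sets score near the false-positive floor, and
partially diverged partitions land in between — the calibration tests pin
all three behaviours.

## Stratum-adjusted correlation (SCC)

All Hi-C matrices share a strong decay of contact frequency with genomic
distance, so a naive correlation between two matrices is dominated by that
common trend. The SCC therefore stratifies entries by diagonal offset
`d = 1..max_dist` (5 Mb by default; the diagonal itself is excluded),
computes a Pearson correlation per stratum on smoothed matrices, and
combines strata with weights `w_d = N_d * sd1_d * sd2_d`. Smoothing is a
`(2h+1) x (2h+1)` mean filter clipped at the matrix edges; the half-width
`h` is chosen per pair as the smallest value in `0..3` at which the score
converges (`|SCC(h+1) - SCC(h)| < 0.01`), falling back to the range maximum
with a warning when it never converges. The hard upper limit of 3 balances
detail against oversmoothing and compute; raising it requires an explicit
opt-in in the pipeline configuration. Genome-wide scores are unweighted
means over chromosomes, and the per-pair `h` is selected per chromosome.

# Group statistics

Pair similarities are compared between groups with the Mann–Whitney U
test: U from rank sums with midranks for ties; exact p by full enumeration
when `n_a + n_b <= 12` without ties, otherwise the normal approximation
with tie and continuity corrections. Tests are two-sided by default with
the direction reported separately, and raw p-values are reported (a
Benjamini–Hochberg column is available but off by default) since each
contrast is interpreted on its own. A fully tied comparison returns p = 1.
The default contrasts are: replicates vs non-replicates; same tissue with
different donors vs different tissues; trio parent–child vs unrelated
same-cell-type pairs; mixed vs single protocol among same-cell-type pairs;
and same vs different restriction enzyme and lab.

One asymmetry needs care: replicate pairs compare single libraries while
non-replicate pairs compare merged (deeper) samples. For null-calibration
experiments, where replicate noise must equal between-sample noise, the
pipeline option `use_merged = FALSE` scores non-replicate pairs on a single
replicate per sample so that both groups see the same depth.

# The synthetic cohort generator

The generator emulates the statistical structure of real Hi-C cohorts so
that every stage is testable without downloads:

* **Partitions.** TAD lengths are i.i.d. log-normal in bins with the
  distribution median pinned to the target (880 kb default) and
  `sigma_log = 0.5`; any heavy-tailed positive law would do, log-normal is
  pinned for reproducibility. Domains are laid left to right with a gap
  after a domain with probability 0.1 (geometric length, mean 2 bins).
* **Counts.** The mean matrix is
  `depth * (1+d)^-alpha * beta^[same TAD] * f^[d > cutoff]` with power-law
  decay exponent `alpha = 1`, within-TAD enrichment `beta = 2`, and
  protocol factor `f = 0.7` beyond 1 Mb for dilution-protocol samples
  (in-situ samples use `f = 1`); counts are Poisson on the upper triangle,
  mirrored. Replicates are independent Poisson resamples of the same mean —
  the simplest model of resequencing one library population (a
  negative-binomial overdispersion knob exists but is off by default).
  `calibrate_depth()` returns the depth at which the coverage gate passes
  comfortably; the default depth of 300 is ample at a few hundred bins.
* **Biological and technical factors.** Each cell type's partition is an
  independent perturbation of a common root: every interior boundary is,
  with the configured rate, shifted by 1–3 bins, deleted or split, with
  invalid edits skipped. Protocol acts through the long-range factor only;
  restriction enzyme and lab are metadata-only by default so the pipeline
  can demonstrate true-negative contrasts. Trio members share a cell type
  but nothing else, reflecting the absence of a heredity signal. All
  randomness flows from one cohort seed through named substreams, so equal
  configurations reproduce cohorts bitwise.

What the generator does *not* emulate — A/B compartments, loops and other
hierarchy above and below the TAD scale, inter-chromosomal contacts,
mappability artefacts, and realistic read-level noise — bounds what passing
tests show about real data: they validate the algorithms and their
contracts, not biological effect sizes.

# Problem sizes and numerical conventions

The test and reproduction runs use a 300-bin (30 Mb) chromosome with 10
cell types and 2 replicates for cohort-scale checks, 500 bins for
planted-recovery and calibration checks, 1000 null draws for single-pair
TADsim calls and 300 for the four-target robustness sweep — sizes chosen so
the full suite exercises every stage at meaningful depth while remaining
quick to run on one CPU. Other conventions: symmetric inputs are validated
to `1e-9` and floating-point asymmetries symmetrised; smoothing uses a
summed-area table with tiny negative cancellation residues clamped to zero;
the TADsim null runs in C++ using R's RNG so seeding is uniform across R
and compiled code.

# Limitations

* Single-resolution, intra-chromosomal analysis; no nested/hierarchical
  domains and only the one dynamic-programming caller (the consensus
  variant across gammas is out of scope).
* The TADsim variant here fixes its window construction and null
  explicitly (segmentation, circular-shift null, strict-inequality p);
  other published variants differ in these details, so absolute coverage
  values are comparable only within one variant.
* The Mann–Whitney normal approximation is inaccurate in absolute terms at
  very small group sizes; the implementation uses exact enumeration there,
  and the approximation only from `n_a + n_b > 12` upward.
* Real-data effect sizes (e.g. how much protocol choice shifts similarity)
  are not calibrated against public cohorts; the generator's protocol
  factor is a plausibility setting, chosen to make the contrast detectable
  at cohort scale, not an estimate.
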