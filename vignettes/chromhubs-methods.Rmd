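---
title: "chromhubs: models and methods"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromhubs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromhubs)
```

This vignette documents the statistical models behind each pipeline stage,
the rationale for default parameters, the design of the synthetic-data
generators, and the numerical decisions that are easy to get subtly wrong.

## Contact-map balancing

Raw Hi-C counts carry multiplicative per-bin biases (mappability, restriction
density, coverage). `kr_balance()` finds weights $w$ such that
$\mathrm{diag}(w)\,A\,\mathrm{diag}(w)$ has equal row sums over unmasked bins
— matrix balancing in the Knight–Ruiz sense. The solver is the Newton /
conjugate-gradient inner iteration of Knight & Ruiz (2013); if it fails to
converge it falls back to symmetric Sinkhorn–Knopp ($w \leftarrow
w/\sqrt{s}$, $s$ the current balanced row sum), which converges linearly but
unconditionally for fully indecomposable nonnegative matrices. Balanced
values are rescaled so the balanced total equals the raw total, keeping
downstream quantities on a read-count-like scale.

Bins whose raw marginal falls below `mask_floor` (default 10) are masked
before balancing: near-empty rows make the balancing ill-conditioned and
their weights meaningless. Masked bins propagate as `NA` through interaction
scores and are excluded from compartment scoring.

Two choices worth noting:

- **Idempotence** is a test invariant: balancing an already-balanced map
  changes weights only within tolerance.
- The balanced matrix is validated against an independent high-precision
  Sinkhorn oracle in the tests; agreement is in the weight *ratios* (the
  overall scale is a convention).

## Interaction, TAD, and compartment scores

The **interaction score** of a bin is its balanced row sum with the diagonal
excluded; replicate reproducibility is the Pearson correlation of two
replicates' score vectors. The **TAD score** of an interval is computed on
raw counts: intra-domain pairs divided by all pairs touching the domain,
same-bin pairs excluded from both; it is invariant to counts entirely outside
the domain and non-increasing in added cross-boundary counts.

**A/B compartments** use the classical eigenvector method at 100-kb bins:
distance-normalize the balanced map (observed over per-distance mean
expected; distances with fewer than 3 unmasked observations are pooled with
the next shorter distance to avoid unstable expected values at the matrix
corners), form the Pearson correlation matrix over unmasked bins, and take
the leading eigenvector. The eigenvector's sign is arbitrary, so it is
anchored to an activity track (e.g. H3K27ac coverage): the sign is flipped if
needed so that positive-score bins have mean activity at least that of
negative-score bins. A constant matrix has an undefined correlation and
raises a degenerate-input error rather than returning noise.

## Loop hubs

Loop anchors become graph nodes after merging anchors that overlap by at
least 1 bp (merged nodes carry the union interval); each loop contributes one
edge, and loops whose two anchors merge into the same node are dropped as
self-edges. Communities come from Louvain modularity maximization
(`igraph::cluster_louvain`, resolution 1) under a fixed RNG seed for
reproducibility. Cluster sizes form a heavy-tailed rank curve; the hub
threshold is the **elbow (tangency) point**: sort ascending, scale both axes
to $[0,1]$, and take the value at the maximum of $x - y$ — the point where a
unit-slope line is tangent to the curve. Ties break to the largest index
(conservative: fewer hubs). Hubs are clusters whose size is *strictly* above
the threshold. Within a hub, anchors are ranked by PageRank (damping 0.85),
which identifies the focal anchor of star-like hubs.

The elbow rule is affine-invariant (scaling all sizes leaves the selected
index unchanged), which the tests assert, and degenerate curves (fewer than 3
values, or all equal) return `max(values)` with a warning so that nothing
passes the strict comparison.

## Differential chromatin-interaction hubs

Given pooled balanced maps for two conditions (dKO depth-rescaled to the WT
total):

1. **Edge selection**: keep bin pairs (diagonal excluded, optional distance
   cap) whose balanced value is strictly larger in the target condition and
   whose combined signal exceeds the weak-interaction floor
   (`(WT + dKO) > 10`); the floor removes the vast sparse background that
   would otherwise dominate clustering.
2. **Clustering**: Louvain on the selected pairs, edge weights taken from the
   reference (target) condition.
3. **1D projection**: each cluster is projected to a contiguous genomic
   region. The seed is the member bin with the highest PageRank (ties to the
   smaller bin index); a member bin is included iff
   $\mathrm{degree}/\mathrm{distance}^2 < 0.5$, with distance measured in
   bins from the seed. The comparator is configurable
   (`projection_comparator`) because the inclusion rule's direction is
   ambiguous as printed — the `<` form is the default; the `>=` form inverts
   membership. The region is the min–max span of included bins.
4. **Significance**: a one-sided paired Wilcoxon signed-rank test compares
   the region's internal WT vs dKO balanced values (upper-triangle pairs);
   regions with $p < 10^{-7}$ are reported.

Two properties discovered during validation are worth recording. First, the
end-to-end p-value is *not* monotone in the planted effect size: a stronger
fold raises node degrees, the degree/distance² rule then excludes more bins,
and the projected region shrinks — fewer internal pairs, larger p. The
monotonicity one expects holds at a *fixed* region
(`test_region_significance`), and the tests assert it there. Second, null
region p-values are conservative rather than uniform (regions are selected
around PageRank seeds), so the null-calibration test asserts a binomial upper
bound on the sub-threshold fraction instead of uniformity.

## Exact Wilcoxon signed-rank with ties

Balanced contact values in a region are often equal across conditions
(masked or identical bins), producing tied absolute differences —
`stats::wilcox.test` refuses exact computation in that case.
`wilcox_signed_rank()` computes the exact null distribution of the
signed-rank sum by dynamic-programming convolution: mid-ranks are doubled to
integers, and the distribution over all $2^n$ sign assignments is built by
successive convolution, for up to $n = 25$ nonzero differences. This handles
fully tied cases exactly (ten positive unit differences give
$p = 2^{-10} = 0.0009765625$). Above $n = 25$ the normal approximation with
tie-corrected variance and continuity correction is used. The implementation
is tested against exhaustive $2^n$ enumeration (tied), `wilcox.test`'s exact
branch (untied), and its corrected-normal branch (large $n$).

## Motif model

A PWM stores per-position base probabilities (pseudocount-smoothed at
construction so log-odds are finite) and natural-log odds against a uniform
background. `score_window()` scans every offset on both strands and returns
the best summed log-odds; `N` contributes 0. The built-in Tcf/Lef PWM has
consensus `ATCAAAG` with maximum score 9.662. Peaks are classified on the
±100 bp window around the summit: **Motif+** when the best hit is strictly
above 7, **Motif−** when strictly below 3, **MotifInt** otherwise. The
strictness of both inequalities is pinned by tests that place the achieved
best score exactly at a threshold.

A useful closed form for interpreting background rates: only the exact 7-mer
consensus scores above 7 for a sharp PWM, so a random 201-bp window scanned
on both strands is Motif+ with probability
$1 - (1 - 2 \cdot 4^{-7})^{195} \approx 2.4\%$ — the measured false-positive
rate of the scanner on background-only synthetic peaks matches this
analytically, and the tests assert agreement with the closed form rather
than an arbitrary small number.

## Super-enhancers, element–gene links, lineage genes

Acetylation islands separated by at most 12.5 kb are merged (ROSE-style
stitching, idempotent by construction); stitched regions are ranked by summed
island signal and thresholded by the same elbow rule as hubs. The
signal-to-noise ratio (island reads / total reads in the span) guards against
differential calls driven by inter-island background.

Elements link to genes by three composable rules: the **window** rule
(element within TSS−50 kb … TES, strand-aware), the **closest** rule for
window orphans (midpoint to nearest TSS/TES, ties reported and flagged), and
additive **loop** links (element on one anchor, promoter on the other).
Accessibility and expression changes combine into concordance classes C1–C4
(up/up, down/up, up/down, down/down).

Lineage-enriched genes use edgeR quasi-likelihood F-tests (robust, TMM
normalization) pairwise between lineages; a LEG must win (≥ 5-fold, FDR
≤ 0.01) at least 5 of 6 comparisons and have within-lineage CV < 1. The CV is
computed on raw counts, so divergent library depths can exclude a perfectly
consistent gene — the tests build exactly that case. Outlier replicates are
flagged iteratively (worst below-threshold replicate removed, then
re-evaluate), because a single bad replicate also depresses its lineage
mates' leave-one-out correlations.

## Synthetic-data generators and their realism

Every generator is a pure function of its specification and seed, and emits a
truth record so tests never re-derive ground truth.

- **Contact maps**: expected matrix = depth-scaled distance decay
  $(1+d)^{-1}$ × compartment checkerboard × TAD blocks + focal loop
  additions; the differential-hub region's internal expectations are
  multiplied by the fold in one condition. Replicates are independent Poisson
  draws — at the shallow depths used here counting noise dominates replicate
  variability, so Poisson (rather than negative binomial) is the honest
  model.
- **Peaks/sequences**: one uniform-random contig with evenly spaced peaks; a
  chosen fraction receives a motif instance sampled from the PWM on a random
  strand near the summit. Instances are rejection-sampled until their own
  log-odds score exceeds the direct-binding cutoff: a "direct-binding site"
  that does not contain a functional motif occurrence would be mislabeled
  truth, and for a PWM with per-position consensus probability 0.994 about 4%
  of unconditional draws carry a disqualifying mismatch.
- **Expression**: log-normal baseline means shared across lineages, negative
  binomial counts (dispersion 0.1), planted markers at 10-fold in their
  lineage. Ten-fold is the magnitude of real lineage markers and is chosen
  a priori from a power analysis: planting exactly at the 5-fold calling
  threshold makes each pairwise win a coin flip for any near-unbiased fold
  estimator, capping recall near 0.2 regardless of implementation; recovery
  of a planted effect is only a meaningful test when the effect is clearly
  inside the detection region.
- **Loop universes**: planted hubs are dense anchor near-cliques (pairwise
  loops with probability 0.8 plus a random spanning tree for connectivity)
  among isolated two-anchor loops.

## Numerical decisions

- BED/BEDPE coordinates are 0-based half-open in files and in `loop_set`;
  conversion to 1-based `GRanges` happens only at the reader boundary.
- Fold changes use TMM-normalized group means with a 0.5 pseudocount; the
  pseudocount means an exact 5-fold mean ratio measures slightly below 5 —
  boundary tests account for this.
- `relative_loop_strength` does **not** depth-normalize internally; equal
  sequencing depth is a documented precondition, so uniformly halving one map
  doubles the reported ratio.
- `read_pwm` applies no pseudocount by default: stored probabilities already
  include the construction-time smoothing, and re-smoothing breaks round
  trips in the 4th decimal.
- Elbow ties break to the largest index; hub membership is strict (`>`);
  motif thresholds are strict on both sides; all three are pinned by
  boundary tests.

## Limitations

- Hi-C realism: no restriction-fragment structure, no trans contacts, no
  replicate overdispersion; single-chromosome maps only.
- The differential-hub projection rule follows the printed degree/distance²
  inequality; its comparator direction is configurable because the printed
  form excludes well-connected bins, which shrinks regions at strong effect
  sizes (see above).
- The compartment method is the first-eigenvector classic; it does not
  resolve sub-compartments and can mix signs on chromosomes whose leading
  eigenvector tracks arm-scale coverage rather than compartments.
- LEG calling at the 5-fold boundary is power-limited by construction (see
  the generator section); results within ~1.5× of the fold threshold should
  be treated as uncertain.
- Exact signed-rank computation is $O(n \cdot \sum r)$ and is capped at
  $n = 25$; beyond that the tie-corrected normal approximation is used.
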