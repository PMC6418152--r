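---
title: "Interactivity profiles and highly interacting regions from Hi-C maps"
author: "hirscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interactivity profiles and highly interacting regions from Hi-C maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hirscan)
```

## The model

An intra-chromosomal Hi-C contact map is a symmetric matrix $C$ whose entry
$C_{ij}$ counts how often the fixed-size genomic bins $i$ and $j$ were found
crosslinked in a cell population. `hirscan` treats the map as a weighted
network: bins are nodes and contact frequencies are link weights. Because
contact frequency decays strongly with genomic distance, raw counts mostly
encode linear proximity; what is of interest is *excess* affinity. The
expected contact frequency at bin distance $d$ is taken as the median of all
entries on the $d$-th diagonal, and the weight of a link is the
observed-minus-expected count

$$A_{ij} = \max\!\left(C_{ij} - \mathrm{med}_{|i-j|},\, 0\right),$$

clamped at zero because a below-expected contact carries no excess affinity
and a jump probability cannot be negative. Subtraction (rather than division
by the expected value) is the default because it yields a much larger dynamic
range in the resulting profile; the `oe_divide` form is available for the
between-class contact analysis, where values above one directly read as
"more often in contact than expected at that distance".

Dividing each row of $A$ by its row sum gives a row-stochastic transition
matrix $W$, the law of a random walker jumping between bins proportionally to
excess contact. Its stationary distribution $p^\infty$, fixed by
$p^\infty = p^\infty W$, is the left eigenvector of $W$ for eigenvalue one,
normalized to sum to one. (For a stochastic matrix the eigenvalue of interest
is exactly one — it is the largest in modulus; descriptions of the same
quantity sometimes label it the "smallest" in other orderings, but there is
no ambiguity about which eigenvector is meant.) $p^\infty_i$ is the long-run
probability of finding the walker at bin $i$ and serves as a per-bin
**interactivity score**: the share of excess contacts a bin participates in.

Because the clamped weights are symmetric, the stationary distribution has a
closed form, $p^\infty_i = \sum_j A_{ij} / \sum_{kl} A_{kl}$. The package
exposes three routes — `eig` (the eigendecomposition, the default), `rowsum`
(the closed form) and `power` (iteration of $p \leftarrow pW$) — and the test
suite requires them to agree elementwise to $10^{-8}$ on random connected
networks. Keeping the closed form as a live cross-check guards the linear
algebra; keeping the eigensolver as the default keeps the implementation
honest for inputs where symmetry is ever relaxed.

**Masked bins and components.** Unmappable bins (all-zero rows; or a
user-supplied mask) are excluded before the diagonal medians are taken, since
they would drag the medians toward zero. Rows whose clamped weights sum to
zero are masked likewise. If the clamped weight graph splits into several
connected components the stationary distribution is not unique; `hirscan`
computes it per component and weights each component by its share of total
clamped weight, which preserves the "share of contacts" reading and is
deterministic. Self-contacts (the main diagonal) are retained by default;
`dropDiagonal = TRUE` removes them before clamping.

## Calling highly interacting regions

A **HIR** is a maximal run of at least `minBins = 5` consecutive bins whose
stationary value *strictly exceeds* the chromosome's 90th percentile
(`q = 90`), percentiles being computed over unmasked bins with the standard
linear-interpolation quantile. At the native 5 kb resolution this is "five
or more consecutive 5 kb bins above the top-10% cut-off". A masked bin
terminates a run: interactivity is not extrapolated across unmappable gaps.
Lower-interactivity control tiers (percentile bands 0–30, 30–50, 50–80) are
produced by the same run rule via `tierRegions()`.

Each HIR gets two flank pairs for contrast analyses: `F1`, the two
immediately adjacent intervals of the HIR's own length, and `F2`, two
same-length intervals whose proximal edges sit 100 kb away. Both are
reported throughout because adjacent and offset flanks answer slightly
different questions (local spill-over versus background at a distance);
flanks are clipped at chromosome ends and flagged when clipped or when they
land on another HIR.

## Signal tracks: clamp-then-percentile normalization

Heterogeneous tracks (ChIP-seq of chromatin proteins, histone marks, DNase,
MNase, methylation) are made comparable by a two-step normalization per
dataset: every value below the genomic average (the mean of non-missing
bins, after averaging the track down to the working 5 kb bins) is set to the
average, and each remaining value is replaced by its percentile among the
above-average values (max-rank on ties, scaled so the maximum is exactly
100). The result is a 0–100 scale where 0 means "at or below genomic
background" and 100 "the genome-wide maximum". Datasets that are more than
50% missing, or whose mean normalized enrichment over HIR bins is below 2
(i.e. essentially background at HIRs), are excluded before multivariate
analysis — both rules are exposed in `excludeDatasets()` with their reasons
recorded.

Genome-scale association between a track and the profile is summarized by a
Spearman rank correlation of 100 kb window averages (`spearmanVsProfile()`),
pooling windows across whichever chromosomes are supplied. On real human
data one would typically restrict this to a fixed chromosome subset
(e.g. 1, 2, 6, 7, 8, 9, 10, 11, 20, 21, 22, X) via the `chroms` argument.

## Classifying HIRs

The HIR × track matrix of mean normalized enrichments (column-mean
imputation for tracks with no data over a HIR, with the imputation count
logged) is centred, scaled to unit variance per column, and projected onto
its leading principal components; six components are kept by default, and a
broken-stick criterion (`brokenStick()`) is available when a data-driven
count is preferred. Component signs follow a fixed convention (largest
loading positive) so scores are reproducible across row orders. Ward
clustering (`ward.D2` on Euclidean distances between scores) cut at `k = 6`
defines the HIR classes; labels are renumbered by decreasing class size so
that "class 1" is stable. Class labels are arbitrary names — matching them
to biological archetypes (Polycomb-repressed, actively transcribed,
enhancer-rich open chromatin, ...) is a post-hoc interpretation step, not
something the clustering itself guarantees.

## Annotation overlap and between-class contacts

`overlapCount()` compares the number of annotation features sharing ≥ 1 bp
with a region set against the uniform-genome expectation
$n_\text{features} \times \text{coverage fraction}$ — features are treated
as points for counting, matching the "expected number in regions the size
of the set if features were evenly distributed" reading. The genome size is
always the sum of the supplied chromosome lengths, never a hardcoded
constant. `tadPosition()` labels each HIR `border` (it covers a TAD start or
stop coordinate, half-open convention), `inside` (fully contained in a TAD)
or `outside`; the three labels are exhaustive and mutually exclusive.
`expressionSummary()` assigns genes to HIRs by ≥ 1 bp overlap and reports
per-HIR and per-class mean RPKM, gene counts and gene lengths against the
all-gene baseline. `classContacts()` extracts observed/expected values for
all same-chromosome bin pairs within and between classes (self-pairs
excluded, inter-chromosomal pairs never considered) and, per class, against
10 000 random unmasked non-member bins drawn with a caller-supplied seed.

## The synthetic generator

`simulateMap()` emulates the features of a real intra-chromosomal map that
this method actually consumes: a power-law distance decay
$\mu_{ij} = \lambda_0 (1+|i-j|)^{-\alpha}$, Poisson-distributed integer
counts, symmetry, and planted "hub" blocks whose *pairwise* (inter-block)
contacts are boosted $\beta$-fold — the long-range excess-contact signature
that the stationary distribution is designed to detect. Defaults: 500 bins
of 5 kb, $\alpha = 1$ (the typical decay regime), $\lambda_0 = 1000$ (a
deeply sequenced 5 kb map, on the order of $10^3$ counts in diagonal bins),
five disjoint 8-bin hubs (8% of bins, comfortably inside the top-10%
calling band), $\beta = 5$. The choice of $\lambda_0$ matters: the planted
signal grows linearly in $\lambda_0$ while clamped Poisson noise grows as
$\sqrt{\lambda_0}$, so shallow maps (two orders of magnitude fewer counts)
genuinely cannot support reliable hub recovery at $\beta = 5$ — a property
of the method on shallow data, not of the implementation.

What the generator does **not** emulate: TAD blocks and A/B compartment
structure, balancing artefacts, copy-number variation, translocations, and
distance-dependent noise correlations. Passing the recovery tests therefore
demonstrates correctness of the algorithmic chain under the stated model,
not performance on any real cell line. `simulateTracks()` plants per-class
enrichment archetypes plus Gaussian noise (sd 5 on the 0–100-like scale) on
the hub bins so the classification chain can be tested with known ground
truth.

## Numerical choices and degenerate inputs

* Percentiles: linear interpolation (type 7), the dominant convention.
* "Exceeding" a threshold is strict (`>`); tier bands are `(lo, hi]`, with
  `lo = 0` including the minimum.
* Even-count medians: midpoint of the central order statistics.
* Eigen route: the eigenvalue closest to one must be within $10^{-6}$ of
  one, otherwise an error; power iteration: tolerance $10^{-12}$, cap
  $10^5$ iterations, non-convergence is an error.
* All-negative or all-masked maps are an "empty network" error; a single
  surviving bin has $p^\infty = 1$.
* Ward ties and label order: deterministic (renumber by size, then lowest
  row index).
* t tests: Welch and pooled-variance both reported; with fewer than two
  regions on either side, or zero variance on both, the statistic is `NA`
  rather than a fabricated number.
* Writers emit 17 significant digits so write/read round trips are exact
  for representable values; the pipeline manifest excludes timestamps so
  identical configurations reproduce byte-identical output trees.

## Problem sizes used in the checks

The shipped tests and the acceptance script run entirely on synthetic data:
100 random networks of up to 50 bins for the method-agreement check, 500-bin
maps over 20 seeds for hub recovery, a 3 Mb synthetic genome with $10^4$
point features for the overlap null, and 60 × 8 feature matrices for the
classification recovery. These sizes were chosen so the whole suite runs in
well under a minute on one core while keeping every stochastic check
comfortably away from its decision boundary.

## Known limitations

* Inter-chromosomal contacts are out of scope by design; profiles are per
  chromosome.
* No matrix balancing (ICE/KR) is performed; the package accepts raw or
  pre-balanced input and records which was supplied.
* The stationary distribution reflects *excess* contact mass, so two
  chromosomes' profiles are each normalized to sum to one and are not
  directly comparable in absolute level.
* cooler/HDF5 containers are not read directly; export such maps to COO
  text (`cooler dump`-style triples) first.
* The six-component/six-class defaults mirror a specific analysis of
  GM12878-scale data; for other datasets use `brokenStick()` and judge `k`
  from the dendrogram rather than trusting the defaults.
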