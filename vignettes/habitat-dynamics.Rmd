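---
title: "Niche modelling and habitat-suitability dynamics with nichedyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Niche modelling and habitat-suitability dynamics with nichedyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichedyn)
```

## What the package models

`nichedyn` implements the analysis chain used to ask how the climatically
suitable range of a plant taxon shifts under future emission scenarios:
occurrence records and gridded environmental layers go in; suitability
surfaces, four-class habitat maps, area-change indicators, centroid
trajectories and protected-area coverage come out. Every stage is an exported
function on plain containers (`grid_spec`, `nd_raster`, `env_stack`,
`occurrence_set`), and a seeded synthetic-data module generates inputs with
known ground truth so the whole chain is testable offline.

## The maximum-entropy suitability model

The core model is a MaxEnt-type Gibbs distribution over background cells.
Environmental variables are expanded into feature classes — linear (L),
quadratic (Q), pairwise products (P), forward/reverse hinges (H) and step
thresholds (T), all min–max scaled to $[0,1]$ on the background — and the
model assigns each cell $z$ the raw probability

$$q_\lambda(z) = \frac{e^{\lambda \cdot f(z)}}{Z_\lambda}, \qquad
Z_\lambda = \sum_{b \in \text{background}} e^{\lambda \cdot f(b)} .$$

Coefficients maximize the regularized training gain

$$G(\lambda) = \bar f_{\text{presence}} \cdot \lambda
  - \log \tfrac{1}{B}\textstyle\sum_b e^{\lambda \cdot f(b)}
  - \sum_j \beta_j |\lambda_j|,$$

normalized so the null model has $G(0) = 0$. The per-feature penalty is
$\beta_j = \mathrm{RM} \times \mathrm{base}(\mathrm{class}_j, m) \times
s_j/\sqrt{m}$, with $m$ the presence count, $s_j$ the presence standard
deviation of feature $j$, and the base penalties interpolated on the
conventional anchors (L/Q/P on $\{(10,1),(30,0.2),(100,0.05)\}$, hinge
constant $0.5$, threshold on $\{(10,2),(100,1)\}$); `base_penalty()` exposes
the table. The optimizer is cyclic coordinate-wise proximal descent
(Newton step + soft-thresholding) with per-coordinate backtracking, which
makes the gain provably non-decreasing — a property the test suite asserts on
every fit trace. Convergence is a full sweep improving the gain by less than
$10^{-6}$; the sweep cap is 500.

The *logistic* output rescales the raw density as
$c\,q / (1 + c\,q)$ with $c = e^{H}$, $H$ the entropy of the raw background
distribution. This is the convention under which a completely uninformative
model scores exactly $0.5$ everywhere, which in turn is what makes the fixed
$0.1/0.3/0.5$ classification cut-offs meaningful.

### Tuning and evaluation

`tune_maxent()` evaluates the full grid of regularization multipliers
$\{0.5, 1.0, \dots, 4.0\}$ by feature combinations
$\{L, H, LQ, LQH, LQPH, LQPHT\}$ — 48 candidates — and selects the one with
$\Delta\mathrm{AICc} = 0$, breaking ties by higher test AUC, then fewer
parameters, then lexicographic feature combination. AICc counts $k$ as the
number of nonzero coefficients and flags candidates with $k \ge n-1$ as
invalid. AUC is the rank-based (Mann–Whitney) statistic with ties counted
one half; the conventional banding (poor $\le 0.7 <$ moderate
$\le 0.9 <$ high) is attached as a label. Replicate schemes follow sample
size: genus-level subsampling holds out 25%, species-level models hold out
30% ($n \ge 50$) or 40% ($20 \le n < 50$) and fall back to bootstrap below
$n = 15$; the uncovered $15 \le n < 20$ band maps to 40% with a warning
because no published rule exists for it.

### Variable screening

Screening mirrors standard practice: an initial model's percent
contributions (gain credits accumulated per variable during coordinate
descent, products split 50/50) remove zero-contribution variables, then
`pearson_filter()` walks correlated pairs ($|r| \ge 0.80$) in descending
$|r|$ and drops the lower-contribution member — unless it is protected by the
`keep` argument on ecological grounds, in which case its partner is dropped
instead. The greedy pairwise order (not clique elimination) was chosen for
reproducibility; the filter is deterministic given the stated ordering, and
replicate contribution tables are combined by arithmetic mean.

## Niche overlap

Occurrence points are projected into a shared environmental space: variables
are z-scored, a single PCA is fitted on the pooled points of all species (or
on a background table, via the `background` argument), and each species'
(PC1, PC2) scores are turned into a Gaussian kernel density evaluated at the
cell centers of one shared $35 \times 35$ grid whose extent is the pooled
score range plus a 10% margin — so disjoint clouds still fall on-grid. The
35-cell resolution is the smallest that remains stable for species with very
few records (down to $n = 8$) without washing out structure. Bandwidths use
the normal-reference rule per axis per species, floored at 1% of the axis
extent for degenerate clouds. Schoener's overlap is then

$$D = 1 - \tfrac12 \sum_{i=1}^{n} \lvert p_{x,i} - p_{y,i} \rvert,$$

on the renormalized grids ($\sum_i p_{x,i} = 1$, $n = 1225$). Because the
"maximum value method on variable gradients" reading of the integration step
is also defensible, `overlap_matrix(mode = "gradient")` provides the
alternative: per-variable 1-D densities on shared 35-point grids, pairwise D
aggregated by the maximum across variables. The two modes answer slightly
different questions (joint niche vs. most-shared single gradient) and neither
is asserted to be canonical. No availability (background) weighting is
applied to the occurrence densities. Genus-level and species-composite
predictions are compared with `composite_max()` (cell-wise maximum) and
`consistency_metrics()` (Pearson r over jointly valid cells plus a Jaccard
overlap ratio of the $p \ge 0.5$ areas).

## Classification and dynamics indicators

`classify_suitability()` applies the printed boundary semantics exactly:
unsuitable $p < 0.1$, poor $0.1 \le p < 0.3$, moderate $0.3 \le p < 0.5$,
high $0.5 \le p \le 1$ (lower bounds inclusive, upper exclusive, the high
class closed at 1). "Suitable" for transition accounting is the binary union
$p \ge 0.1$: stability indices in the high-90s alongside class-level
degradation flows are only consistent with the binary reading, so
`transition_summary()` books expansion, contraction and stability on that
mask while also returning the full $4\times4$ class flow matrix. Areas are
geodesic on a sphere of radius 6371.0088 km
($R^2 \Delta\lambda (\sin\varphi_N - \sin\varphi_S)$ per cell), reported in
$10^4$ km² — projection-free and accurate to well under a percent at the
working extents. The indicators are

* RCR $= (A_{\text{final}} - A_{\text{initial}})/A_{\text{initial}} \times 100\%$,
* CI $= (A_{\text{expansion}} + A_{\text{contraction}})/A_{\text{initial}} \times 100\%$,
* SI $= A_{\text{stable}}/A_{\text{initial}} \times 100\%$,
* SDR $= \min(A_{\text{expansion}}, A_{\text{contraction}}) /
  (A_{\text{expansion}} + A_{\text{contraction}}) \in [0, 0.5]$, defined as 0
  when nothing changes.

Indicator values are kept at full precision; reporting rounds half away from
zero to two decimals, and `period_mean()` averages the *rounded* per-period
values — the arithmetic that reproduces published summary rows exactly (a
full-precision mean can differ in the last digit).

## Geography

High-suitability centroids are area-weighted means of cell-center
coordinates over the binary high-class mask (geometric center of the
extracted area, not suitability-weighted). Migration distances are haversine
great circles on the same sphere radius; per scenario the consecutive-period
displacements give $n = 3$ distances, compared across scenarios with a
Kruskal–Wallis test implemented with mid-ranks and the tie-correction factor
$1 - \sum(t^3 - t)/(N^3 - N)$, $p$ from the $\chi^2$ upper tail. Gap analysis
takes moderate + high cells as the priority conservation area and counts a
cell as protected iff its center lies inside a polygon (even-odd rule); the
discretization error is at most the one-cell ring around polygon boundaries,
which the synthetic-polygon tests bound explicitly.

## What the synthetic data emulate — and what they do not

`make_env_stack()` builds smooth random fields (white noise low-pass filtered
with a 5-cell kernel) and imposes requested pairwise Pearson correlations
exactly by empirical orthogonalization, on a default desk-scale grid of
100×120 cells at 0.05° (≈5 km). `sample_occurrences()` draws cells
proportionally to a known inverse-logit linear–quadratic suitability truth
and adds within-cell jittered duplicates, so grid thinning — not coordinate
de-duplication — is what removes them. `make_scenario_set()` flips a planned
number of frontier cells across the 0.1 boundary per transition, making
$A_{\text{expansion}}$ and $A_{\text{contraction}}$ known *by construction*
(the realized per-transition areas are returned as a ground-truth manifest;
on a lat/lon grid equal cell *counts* are not equal *areas*, so exact
assertions use the manifest). `make_species_pair()` places two occurrence
clouds whose extracted environmental values are bivariate normal with means a
chosen number of pooled standard deviations apart, giving known D extremes;
`make_protected_polygons()` emits per-cell rectangles until a coverage target
is met within one cell-area.

These generators deliberately do **not** emulate: the covariance structure of
real bioclimatic variables, spatially biased sampling effort, georeferencing
error, GCM downscaling artifacts, or irregular protected-area geometry.
Passing tests therefore demonstrate that the estimators recover known truth
under clean conditions — correctness of the machinery — not that any
particular field dataset would yield the same headline numbers.

## Numerical choices and defaults

* Nodata sentinel −9999; comparisons use the stored sentinel exactly; nodata
  cells are excluded from all area sums, including over ocean-like masks.
* Half-open cell membership $[W, E) \times [S, N)$, so boundary points belong
  to exactly one cell; within-cell thinning keeps the first record in input
  order (deterministic and auditable).
* Grid alignment requires all five header fields to agree within $10^{-9}$
  degrees; nothing resamples silently.
* Hinge/threshold knots: 20 per variable per direction by default, evenly
  spaced in the open background range (no degenerate all-zero feature);
  reduce for small fixtures.
* Background: all valid cells up to 10,000, otherwise a seeded subsample.
* Optimizer tolerance $10^{-6}$ per sweep, 500-sweep cap, presence-SD floor
  $10^{-4}$ in the penalty so constant features stay at zero.
* KDE bandwidth: `bw.nrd` per axis, floored at 1% of extent.
* Rounding for reported percentages: half away from zero, two decimals.

The test suite and the examples run at deliberately desk-scale problem sizes
(grids of $\le$ 120×100 cells, background $\le$ 4000, presences in the
hundreds, tuning menus trimmed where the full 48-candidate grid is not itself
the property under test); the same code paths scale to full-resolution
inputs unchanged.

## Known limitations

* ESRI ASCII is the only raster format read and written; GeoTIFF inputs
  should be converted upstream. No reprojection or resampling is provided —
  all layers must share one geographic grid.
* Logistic output only (no cloglog), no categorical features, no clamping or
  extrapolation diagnostics (MESS-style maps).
* Niche-overlap significance (equivalency/similarity permutation tests) is
  out of scope; the package quantifies overlap, not its null distribution.
* Polygon coverage uses cell centers, not fractional-cell overlay; for very
  coarse grids relative to polygon size the one-cell-ring error can matter.

## A compact worked run

```{r pipeline, eval = FALSE}
cfg <- system.file("extdata", "demo_config.yaml", package = "nichedyn")
res <- run_pipeline(cfg, outdir = "demo_run")
res$dynamics              # per-transition RCR/CI/SI/SDR + period means
res$scenario_set$truth    # the generator's realized ground truth
res$gap$coverage_pct      # protected coverage of the priority area
```

The run directory contains every intermediate artifact as plain text:
`.asc` layers and predictions, the thinning report, the correlation matrix,
the 48-row (or trimmed) tuning table, indicator and gap tables, and a JSON
manifest of the ground truth the synthetic inputs were built to satisfy.
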