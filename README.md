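# nichedyn

Species distribution modelling and habitat-suitability dynamics for
biogeographers and conservation analysts working on regular
latitude/longitude grids. The package covers the full analysis chain used in
climate-change range studies of plant taxa:

1. **Occurrence handling** — CSV readers, grid-cell spatial thinning (one
   record per ~5 km cell at genus or species level), before/after reports.
2. **Variable screening** — extraction at points, removal of
   zero-contribution variables, Pearson `|r| >= 0.80` filtering with an
   ecological-importance override.
3. **A from-scratch maximum-entropy model** — the Gibbs distribution
   `q(z) = exp(lambda . f(z)) / Z` over background cells, with L/Q/P/H/T
   feature classes, per-feature L1 penalties
   `beta_j = RM * base(class, m) * s_j / sqrt(m)`, monotone coordinate-wise
   proximal descent, logistic output `c*q/(1 + c*q)` with `c = exp(H)`,
   AICc tuning over the 8 RM x 6 FC grid, AUC banding, jackknife gains,
   response curves, and percent contributions.
4. **Niche overlap** — Schoener's
   `D = 1 - 0.5 * sum_i |p_x,i - p_y,i|` on shared 35 x 35 kernel-density
   grids in PCA environmental space (or per-variable gradient mode),
   species-composite maps by cell-wise maximum, genus-vs-composite
   consistency metrics.
5. **Dynamics** — four-class suitability maps (cuts 0.1 / 0.3 / 0.5),
   geodesic per-class areas, transition accounting, and the indicator set
   RCR / CI / SI / SDR:
   `RCR = (A_final - A_initial)/A_initial * 100%`,
   `CI = (A_exp + A_con)/A_initial * 100%`, `SI = A_stable/A_initial * 100%`,
   `SDR = min(A_exp, A_con)/(A_exp + A_con)`.
6. **Geography** — area-weighted centroids of highly suitable habitat,
   haversine migration distances, Kruskal–Wallis scenario tests,
   protected-area gap analysis.
7. **Synthetic data with known ground truth** — correlated smooth random
   fields, occurrences sampled from a known suitability function (with
   within-cell duplicates), scenario sequences with exactly planned
   expansion/contraction, two-species niche clouds with controlled
   separation, and protected polygons with a known coverage target — so the
   entire pipeline is testable with no downloads.

Everything reads and writes plain text (ESRI ASCII grids, CSV, GeoJSON,
YAML, JSON). See the vignette `vignettes/habitat-dynamics.Rmd` for the
methods and all numerical conventions.

## Worked example

```r
library(nichedyn)

stack <- make_env_stack(seed = 1, n_vars = 4, corr_pairs = list(list(1, 2, 0.95)))
truth <- truth_model(list(Bio1 = c(2, -1.5), Bio3 = c(1.5, 0)), intercept = 0.5)
occ <- sample_occurrences(truth, stack, n = 300, duplicate_rate = 0.3, seed = 2)
occ_thin <- thin_occurrences(occ, stack$spec, level = "genus")
tail(thinning_report(occ, occ_thin), 2)
#>        species n_before n_after
#> 1 synthetic_sp      300     206
#> 2        Total      300     206
```

300 raw records fall in 206 distinct grid cells; thinning keeps one per
cell. An initial model ranks variables, the correlated pair is filtered, and
the RM x FC grid is tuned by AICc:

```r
pres <- extract_at_points(stack, occ_thin)
bg <- background_table(stack, max_background = 3000, seed = 3)
contrib <- percent_contribution(fit_maxent_on("LQ", pres, bg, rm = 1, hinge_knots = 5))
round(contrib, 1)
#> Bio1 Bio2 Bio3 Bio4
#> 62.6  0.1 33.6  3.7
vars <- pearson_filter(pres[, drop_zero_contribution(names(contrib), contrib)],
                       rank = contrib)
as.character(vars)   # Bio2 (r = 0.95 with Bio1, lower contribution) is dropped
#> [1] "Bio1" "Bio3" "Bio4"

tn <- tune_maxent(pres[, vars], bg[, vars], rm_grid = c(0.5, 1, 2),
                  fc_menu = c("L", "LQ"), hinge_knots = 5, seed = 4)
tn
#> <tune_result> 6 candidates; selected FC = LQ, RM = 0.5 (AICc 3151.91, test AUC 0.755)
```

The fitted model predicts a logistic suitability surface; classification and
a planned three-period scenario give the dynamics indicators (areas in
10^4 km^2, percentages rounded to 2 decimals):

```r
suit <- predict(tn$model, stack)
cls <- classify_suitability(suit)
round(area_by_class(cls), 2)
#>     unsuitable           poor       moderate           high total_suitable
#>           4.97           8.24          10.77           8.92          27.92

scen <- make_scenario_set(suit, list(SSP585 = list(
  list(period = "2050s", expand = 25, contract = 5),
  list(period = "2070s", expand = 10, contract = 10),
  list(period = "2090s", expand = 2, contract = 20))), seed = 5)
dynamics_table(scen)
#>   scenario    transition   rcr   ci    si  sdr
#> 1   SSP585 current-2050s  0.20 0.30 99.95 0.17
#> 2   SSP585   2050s-2070s  0.00 0.20 99.90 0.50
#> 3   SSP585   2070s-2090s -0.18 0.22 99.80 0.09
#> 4   SSP585   period_mean  0.01 0.24 99.88 0.25
```

Reading: the suitable range first grows by 0.20% (expansion dominates,
SDR 0.17), then turns over in place (equal gain and loss, SDR 0.50), then
contracts by 0.18%; stability stays above 99.8% throughout. The balanced
2050s–2070s transition shows SDR at its theoretical maximum 0.5. Gap
analysis against polygons built for a 25% coverage target recovers it to
within one cell:

```r
pri <- nd_raster((cls$values >= 2) * 1, stack$spec)
gap_analysis(cls, make_protected_polygons(stack$spec, pri, 0.25, seed = 6))
#> <gap_result> priority 19.68, covered 4.92 (10^4 km^2): coverage 25.00%, gap 75.00%
```

Niche overlap between two synthetic species whose niche centroids sit two
pooled standard deviations apart:

```r
pair <- make_species_pair(separation = 2, n_per_species = 200, seed = 7)
tabs <- split(extract_at_points(pair$stack, pair$occ), pair$occ$species)
overlap_matrix(tabs)
#> <overlap_matrix> 2 species, 0 pair(s) with D = 0
#>       spA   spB
#> spA 1.000 0.361
#> spB 0.361 1.000
```

A config-driven end-to-end run (simulate → thin → screen → tune → predict →
classify → dynamics → centroids → gap → overlap) is available as
`run_pipeline()`; see `inst/extdata/demo_config.yaml`.

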