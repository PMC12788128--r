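# Demo configuration for run_pipeline(): a desk-scale synthetic study with
# known ground truth. All sizes are chosen so the full run finishes in well
# under a minute on one CPU.
seed: 42
grid:
  ncols: 120
  nrows: 100
  xll: 105
  yll: 25
  cellsize: 0.05
simulate:
  n_vars: 5
  corr_pairs:
    - [1, 2, 0.95]      # Bio2 built to correlate 0.95 with Bio1
  truth:
    Bio1: [2.0, -1.5]   # hump-shaped response
    Bio3: [1.5, 0.0]    # monotone response
  intercept: 0.5
  n_occurrences: 250
  duplicate_rate: 0.3
thin:
  level: genus
select:
  threshold: 0.80
  keep: []
tune:
  rm_grid: [0.5, 1.0, 2.0]
  fc_menu: [L, LQ]
  hinge_knots: 5
  test_fraction: 0.25
classify:
  thresholds:
    poor: 0.1
    moderate: 0.3
    high: 0.5
scenarios:
  SSP126:
    - {period: "2050s", expand: 8, contract: 8}
    - {period: "2070s", expand: 5, contract: 2}
    - {period: "2090s", expand: 0, contract: 6}
  SSP585:
    - {period: "2050s", expand: 20, contract: 4}
    - {period: "2070s", expand: 12, contract: 10}
    - {period: "2090s", expand: 2, contract: 18}
protection:
  coverage_target: 0.3
overlap:
  separation: 2
  n_per_species: 200
background: 4000
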