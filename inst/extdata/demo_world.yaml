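
# Demo run: a small self-contained synthetic world exercising every stage.
# Override `out` (and optionally `seed`) before running.
simulate:
  grid_shape: [64, 64]
  cell_size: 10
  n_countries: 6
  n_bcus: 10
  n_habitats: 5
  trend:
    climate: 0.35
    land: 0.005
    marine: -0.02
  metric_missing_rate: 0.15
  seed: 7
options:
  habitat_agg: mean
  clip_quantile: 0.9999
  country_method: mean_of_portions
  outlier_rule:
    rule: iqr
    k: 1.5
out: reefpressure_demo
seed: 7
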