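# inflakinetics

Time-resolved analysis of NLRP3 inflammasome readouts in live-cell
experiments.

Inflammasome activation in macrophages is conventionally scored by endpoint
measurements of a few readouts — ASC-speck formation, IL-1β / IL-18 release,
and LDH leakage as a lysis marker. Endpoint designs can miss the time window
where a trigger acts and give no access to rates. `inflakinetics` implements
the time-resolved alternative for the standard layout (LPS-primed
THP-1-derived macrophages activated with ATP, MSU crystals or nigericin;
imaging every 30 min for 21 h with 12 fields per replicate, n = 5; hourly
supernatant sampling for 24 h), turning raw fluorescence frames and
concentration series into kinetic metrics and small-sample inference:

* **Speck detection** — intensity thresholding (Otsu or fixed), 4/8-connected
  component labeling, and particle filtering with the classic gates: area
  4–100 px, circularity 4πA/P² in 0.50–1.00.
* **Kinetic metrics** — absolute change (first difference, per interval,
  right-edge anchored), acceleration (second difference), sliding-window
  peak selection (best 2-h window by mean, then best point within it), and
  per-replicate peak estimation (mean ± SEM of per-replicate maxima).
* **Normalization** — LDH percent cytotoxicity,
  `100·(treated − spontaneous)/(maximum − spontaneous)` on
  background-subtracted absorbances, and IL-1β:IL-18 ratio trajectories
  with replicate-level error.
* **Inference** — pooled-resampling bootstrap for two-group comparisons
  (mean-difference statistic, plus-one-corrected two-sided p, percentile
  CIs), with a Shapiro–Wilk flag and Benjamini–Hochberg-adjusted columns.
* **Association** — onset / maximum-rate / peak landmarks on
  percent-of-maximum trajectories and pairwise lags between readouts.
* **Synthetic studies** — a generator with known ground truth
  (gamma-pulse speck kinetics, logistic cytokine/LDH release, Poisson and
  lognormal noise, simulated fluorescence frames) driving end-to-end
  validation of every stage.

## Worked example

```r
library(inflakinetics)
library(dplyr)

study <- simulate_study(seed = 42)   # three trigger presets, n = 5, 12 fields

per_replicate_peak(filter(study$panel, readout == "speck_count"))
#>     trigger     readout n mean_peak_value sem_peak_value mean_peak_time_h sem_peak_time_h
#> 1       ATP speck_count 5            51.5          0.888              3.0           0.158
#> 2       MSU speck_count 5           152.8          0.962              5.8           0.255
#> 3 nigericin speck_count 5           159.8          1.244              2.0           0.000
```

The per-replicate peak estimator recovers the generative peak times (3, 6
and 2 h for the ATP-, MSU- and nigericin-like presets) to within one 0.5-h
grid step. The maximum-rate time of the MSU-like speck response comes from
the sliding-window rule applied to the first differences:

```r
msu <- replicate_summary(filter(study$panel, trigger == "MSU",
                                readout == "speck_count"))
sliding_window_max(msu$time_h, msu$mean, window_h = 2, basis = "change")
#>   peak_time_h peak_value window_start_h window_end_h  basis
#> 1         1.5       22.1              1            3 change
```

i.e. the speck count grew fastest (+22 specks/field per 30 min) in the
interval ending at 1.5 h, inside the best 1–3 h window. Comparing triggers
at selected times with the pooled bootstrap:

```r
compare_at_times(study$panel, "speck_count", "MSU", "nigericin",
                 times = c(1, 3, 6), n_boot = 10000, seed = 42)
#>   condition_a condition_b     readout time_h  stat  p_raw   p_bh ci_low ci_high
#> 1         MSU   nigericin speck_count      1 -63.7 0.0014 0.0014  -65.5   -61.4
#> 2         MSU   nigericin speck_count      3  65.5 0.0010 0.0014   62.6    68.4
#> 3         MSU   nigericin speck_count      6 149.8 0.0013 0.0014  146.4   153.1
```

Nigericin leads at 1 h (mean difference −63.7 specks/field); MSU dominates
from 3 h once the nigericin-like signal decays. Cytokine ratios at the end
of sampling separate the presets (≈6 ATP, ≈5.8 MSU, ≈3.7 nigericin at this
seed):

```r
filter(panel_cytokine_ratio(study$panel), time_h == 24)
#>     trigger time_h ratio ratio_sem n
#> 1       ATP     24  6.02     0.337 5
#> 2       MSU     24  5.77     1.081 5
#> 3 nigericin     24  3.72     0.324 5
```

`run_pipeline(pipeline_config(seed = 42), out_dir = "study_out")` runs the
whole chain (simulate → aggregate → kinetics → normalize → test →
associate) and writes every table, the resolved configuration and a run log;
reruns with the same seed are byte-identical.

## Package layout

| Surface | Functions |
|---|---|
| Simulation | `trigger_profile()`, `trigger_presets()`, `study_design()`, `simulate_speck_series()`, `simulate_cytokine_series()`, `simulate_ldh_series()`, `simulate_speck_image()`, `simulate_study()` |
| Detection | `detection_params()`, `classify_and_threshold()`, `measure_particles()`, `count_specks()`, `speck_benchmark()` |
| Kinetics | `absolute_change()`, `acceleration()`, `rate_series()`, `sliding_window_max()`, `aggregate_replicates()`, `replicate_summary()`, `per_replicate_peak()`, `percent_of_max()`, `panel_rates()` |
| Normalization | `background_subtract()`, `percent_cytotoxicity()`, `ldh_percent_panel()`, `cytokine_ratio()`, `panel_cytokine_ratio()` |
| Statistics | `bootstrap_test()`, `shapiro_wilk_gate()`, `compare_at_times()` |
| Association | `landmark_extract()`, `pairwise_lag()`, `lag_matrix()` |
| I/O & pipeline | `read_panel()`, `write_panel()`, `read_frame()`, `write_frame()`, `pipeline_config()`, `run_pipeline()`, `plot_temporal_association()` |

The methods vignette
(`vignettes/time-resolved-inflammasome-readouts.Rmd`) documents the models,
parameter choices, numerical conventions and known limitations.
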