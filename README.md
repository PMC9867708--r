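# bladderclock

Desk-side analytics for glucocorticoid entrainment of the bladder
peripheral clock. Most organs carry an intrinsic circadian oscillator, and
in the bladder its behavioral readout is the day–night rhythm of
functional capacity: nocturnal rodents void smaller volumes more often in
the dark (active) phase and larger volumes less often in the light
(inactive) phase. Glucocorticoid rhythms — corticosterone in the mouse —
are a candidate entraining signal, and probing that hypothesis takes four
kinds of computation that this package implements end to end, together
with synthetic-data generators that provide ground truth for every stage:

* **Rhythmicity screening** of clock-gene expression sampled across the
  day (ZT 4, 8, 12, 16, 20, 24 with replicates). Each gene is fitted with
  a fixed-period cosinor
  `y(t) = M + A cos(2π(t − φ)/24)` and called diurnally rhythmic when
  **MaxCorr > 0.85 and amplitude fold > 1.5**, where MaxCorr is the
  maximum correlation with a cosine template over all phases (equal to the
  cosinor multiple correlation, computed in closed form) and the fold is
  the fitted peak/trough ratio (M + A)/(M − A). Quantile normalization,
  fold-change + ANOVA differential-expression filtering, and sample PCA
  round out the screen.
* **Phase metrics**: acrophase peak/trough timing and signed circular
  phase shifts between conditions, in (−12, 12] h with *negative =
  advance* and an antiphase flag at ±12 h.
* **Bioluminescence reporter traces** (10-min sampling over days):
  moving-average detrending, noise-robust peak detection, period and
  per-cycle amplitude estimation, and quantification of treatment-induced
  phase resets by extrapolating the pre-treatment rhythm.
* **aVSOP micturition analytics**: stain area → volume calibration
  (10–800 µl standard curve), stain position → time at 10 cm/h paper
  speed, 8-h bins anchored to dark onset (ZT14, ZT22, ZT6), volume per
  micturition, volume per hour, ratios to the ZT6 reference bin, and a
  repeated-measures test for the presence of a diurnal rhythm.

Comparison statistics (two-way ANOVA; Sidak, Bonferroni, Tukey and Dunnett
adjustments) and ΔΔCt qPCR quantification support all of the above.

## Worked example

Screen a simulated 10-gene time course (5 cosine genes, 5 flat, noise 10%
of mesor), quantify a reporter phase reset, and summarize a voiding
record:

```r
library(bladderclock)

sim <- simulate_expression_timecourse(expression_sim_config(
  n_rhythmic = 5, n_arrhythmic = 5, noise_sd_frac = 0.1, seed = 7))
calls <- screen_rhythmic_genes(quantile_normalize(sim$matrix))
calls[, c("gene", "acrophase_h", "maxcorr", "fold", "called")]
#>      gene acrophase_h maxcorr fold called
#> 1   gene1       18.56   0.877 2.07   TRUE
#> 2   gene2        7.89   0.934 3.72   TRUE
#> 3   gene3       22.43   0.951 2.58   TRUE
#> 4   gene4        3.37   0.937 2.21   TRUE
#> 5   gene5       11.76   0.949 2.56   TRUE
#> 6   gene6       18.52   0.567 1.16  FALSE
#> ...
```

All five planted rhythms are called (MaxCorr near 1, fold > 1.5); the flat
genes fail both criteria. A 120-h reporter trace given a 10-h phase
advance at t = 60 h:

```r
trace <- simulate_luminescence_trace(trace_sim_config(
  duration = 120, damping_rate = 0.005, noise_sd = 10, phase = 20,
  perturbation_time = 60, perturbation_phase_shift = 10, seed = 7))
res <- treatment_phase_shift(trace$trace, treatment_time = 60)
sprintf("period %.2f h, shift %.2f h", res$pre_period, res$shift_h)
#> "period 24.08 h, shift -10.38 h"
```

The estimated shift is −10.4 h: a 10-h advance (negative by the package's
sign convention), recovered to within half an hour. A 3-day voiding
record from a bladder whose capacity is 40% lower in the dark phase:

```r
ev <- simulate_void_events(void_sim_config(days = 3,
  capacity_modulation = 0.4, event_jitter_sd = 10, seed = 7))$events
nr <- normalize_to_reference(summarize_bins(bin_events(ev, start_zt = 14)))
aggregate(cbind(mean_ul_per_void, ratio) ~ bin, nr, mean)
#>    bin mean_ul_per_void ratio
#> 1 ZT14              198 0.598
#> 2 ZT22              194 0.587
#> 3  ZT6              330 1.000
modulation_from_bin_ratio(mean(nr$ratio[nr$bin == "ZT14"]))
#> 0.38
```

Mean volume per void drops to ~0.6 of the ZT6 reference in the dark-phase
bins, and inverting the bin-ratio model recovers the configured 0.4
modulation.

The methods vignette (`vignettes/bladderclock-methods.Rmd`) documents the
models, defaults, numerical choices and limitations.

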