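---
title: "Methods behind bladderclock: rhythm screening, trace analysis, and micturition analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind bladderclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bladderclock)
```

# Scope

The bladder, like most peripheral organs, runs its own circadian clock, and
glucocorticoid (corticosterone in the mouse) rhythms are one of the cues
that entrain it. Studying that entrainment takes four kinds of quantitative
work, and `bladderclock` implements all of them over a common set of
synthetic-data generators with known ground truth:

1. **Rhythmicity screening** of clock-gene expression time courses sampled
   across the day (`quantile_normalize()`, `cosinor_fit()`,
   `screen_rhythmic_genes()`, `de_filter()`, `pca_scores()`).
2. **Phase metrics**: acrophase peak/trough timing and signed circular
   phase shifts between conditions (`acrophase_peak()`,
   `circular_phase_shift()`, `phase_shift_table()`).
3. **Bioluminescence reporter traces**: detrending, peak detection, period
   and amplitude estimation, and treatment-induced phase resets
   (`detrend_trace()`, `detect_peaks()`, `estimate_period_amplitude()`,
   `treatment_phase_shift()`).
4. **Micturition analytics** for the automated voided stain on paper
   (aVSOP) assay: stain calibration, 8-h binning anchored to dark onset,
   volume-per-void summaries and reference ratios (`fit_standard_curve()`,
   `stain_to_event()`, `bin_events()`, `summarize_bins()`,
   `normalize_to_reference()`, `diurnal_rhythm_flag()`).

Group-by-time statistics (`two_way_anova()`, `posthoc_adjust()`) and qPCR
relative quantification (`ddct_relative_expression()`) support all four.

Throughout, time is Zeitgeber time (ZT): hours since lights-on, under a
14-h light / 10-h dark cycle with dark onset at ZT14 (`light_cycle()`).

# The cosinor model and MaxCorr

A gene's diurnal profile is modeled as a fixed-period cosine,

$$y(t) = M + A\cos\!\big(2\pi (t - \varphi)/P\big) + \varepsilon,$$

with mesor $M$, amplitude $A$ (half the peak-to-trough range), acrophase
$\varphi$ (clock time of the fitted peak) and period $P$ fixed at 24 h. The
fit is linear in $\{\cos(2\pi t/P), \sin(2\pi t/P)\}$, so it is solved by
ordinary least squares; $A$ and $\varphi$ come from the two slope
coefficients.

The rhythmicity statistic is **MaxCorr**: the maximum, over all acrophases,
of the Pearson correlation between the observed series and a cosine
template. Because the templates $\cos(2\pi(t-\varphi)/P)$ sweep out the
whole two-dimensional harmonic space as $\varphi$ varies, that maximum is
identically the multiple correlation coefficient of the cosinor regression,
which is how `cosinor_fit()` computes it in closed form. The dense-grid
search (`maxcorr_grid()`, 0.01-h steps) is kept in the package purely as an
independent oracle; the test suite checks the two agree to $10^{-3}$ on
random series.

A gene is called rhythmic when **MaxCorr > 0.85 and amplitude fold > 1.5**,
both strict, with the fold read as the fitted peak/trough ratio
$(M+A)/(M-A)$ (infinite when the fitted trough is non-positive, 1 for a
flat fit). An alternative reading — observed max/min of the time-point
means — is available via `fold_mode = "observed"`. Replicates enter the fit
as individual samples so that within-time-point scatter counts against
MaxCorr; `average_replicates = TRUE` switches to fitting the means, since
the exact replicate handling of the original MaxCorr recipe is not
reprinted anywhere we could verify.

Degenerate cases are pinned down explicitly: a constant series has
MaxCorr 0 and an undefined acrophase; missing values are an error (a
6-time-point, 3-replicate design is far too small to impute); fewer than
three distinct time points leaves the design matrix rank-deficient and is
an error per gene, recorded in the screen's `error` column rather than
aborting the whole screen.

Differential expression across time uses the companion rule
(max/min time-point mean > 2.0 **and** one-way ANOVA p < 0.05, both
strict). The screen is interpreted within one group across time; comparing
groups per time point is a different contrast that the two-way ANOVA
covers.

# Phase shifts as circular quantities

Acrophases live on a 24-h circle, so differences between conditions are
reported as the shortest signed difference in
$(-P/2, P/2]$: `circular_phase_shift(ref, test)`. The sign convention —
**negative = phase advance** (the test peak occurs earlier) — is stated in
the output because "shifted forward" in common usage does not fix a sign.
An exactly antiphase difference is reported as $+12$ h with an `antiphase`
flag; near that boundary the sign of individual genes is essentially
arbitrary, which is why recovered offsets are summarized as the median of
the shift magnitudes.

With 4-h sampling, the argmax-based peak (`acrophase_peak(mode =
"argmax")`, ties to the earlier ZT) can disagree with the fitted acrophase
by up to half the sampling step; the fitted mode is the default wherever a
cosinor fit exists.

# Reporter trace processing

Simulated and recorded traces are photon counts sampled every 10 min
(`dt = 1/6` h) for several days after synchronization. Processing steps:

* **Detrending.** The baseline is a centered 24-h moving average — one
  full cycle, so the oscillation itself cancels out of the baseline.
  Subtraction gives the detrended trace used for amplitudes; division
  gives the dimensionless "relative luminescence" conventionally plotted
  for destabilized luciferase reporters. Half a window at each end has no
  centered average; those samples are edge-flagged. With
  `extend_edges = TRUE` the interior moving average (already
  oscillation-free) is extrapolated into the edges by a quadratic, which
  trades a little baseline bias at the extremes for a full-length usable
  trace — essential when a recording is split into short segments.
* **Peak detection.** A 2-h boxcar suppresses sampling noise without
  displacing circadian peaks; local maxima at least 18 h apart are kept
  (the higher of two close candidates wins, ties go earlier), and the
  first 12 h are excluded as the post-synchronization transient. Raw
  maxima are then refined to sub-sample precision. The default refinement
  fits a fixed-period cosine with first-order damping regressors
  ($\tau\cos, \tau\sin$ — the linearization of an exponentially decaying
  envelope) over up to a cycle each side of the raw peak and takes the
  local acrophase. Pooling a full cycle of samples per peak is what keeps
  peak times accurate at realistic noise; a 3-point parabolic
  interpolation, the textbook alternative, has an error several times the
  sampling interval at 10–20% noise and would not support period
  estimates to within one sample. Peaks whose usable window is under ¾ of
  a half cycle per side are dropped rather than refined badly, and a
  refinement that moves a peak more than a quarter cycle is treated as a
  spurious candidate and discarded.
* **Period and amplitude.** Period is total elapsed time over total
  cycles between successive peaks (equivalently the mean interval, with
  skipped cycles inferred from the median spacing). Amplitude per cycle is
  half the peak-to-following-trough drop on the detrended trace, which
  tracks damping cycle by cycle.
* **Treatment phase shifts.** A treatment pulse is modeled as a pure
  phase reset: period unchanged, acrophase jumped. The trace is split at
  the treatment time and each side detrended on its own, because a moving
  average computed across the phase jump smears it into the neighboring
  cycles and biases peaks on both sides. Segment peaks are refined by
  symmetric-window pure-cosine fits (damping regressors are collinear with
  the sine term in sub-cycle windows and are omitted). The period is
  pooled from pre- and post-treatment intervals — never across the
  treatment — the expected post-treatment peaks are extrapolated from the
  least-squares line through the pre-treatment peaks, and the shift is the
  circular mean of observed-minus-expected over the post peaks. Negative
  output = advance. On simulated 120-h traces with 10% noise this
  estimator's worst error across resets of $0, \pm4, \pm10, \pm12$ h and a
  range of starting phases is about 0.7 h; the suite asserts a 1-h bound
  and a mean absolute error below 1 h.

# aVSOP micturition analytics

The assay encodes each void as a stain on filter paper moving at
10 cm/h: position is time, stained area is volume via a standard curve
calibrated with saline spots spanning 10–800 µl. `fit_standard_curve()`
refuses calibrations with $r^2 < 0.9$ — a poor curve corrupts every
downstream volume — and `stain_to_event()` keeps but flags volumes outside
the calibrated range, since the range is a calibration statement, not an
exclusion rule.

Events are binned into three 8-h windows centered on ZT14 (dark onset),
ZT22 and ZT6, i.e. [ZT10, 18), [ZT18, 2) and [ZT2, 10), half-open so an
event on an edge belongs to the later bin; days are counted from dark
onset, where a nocturnal animal's behavioral day begins. Summaries per
subject × day × bin are: void count, total volume, mean volume per
micturition (the functional bladder-capacity readout), and volume per hour
(total over the 8-h bin width when recording is complete). Ratios divide
each bin's mean volume per void by the same subject-day's ZT6 value, so
the light-phase reference is identically 1 and a dark-phase capacity drop
shows as ratios below 1. Per-day normalization before averaging across
days is the default; the reverse order is a one-line change on the summary
table and gives the same answer for complete records.

`diurnal_rhythm_flag()` tests for a light–dark difference: days are
averaged within subject × bin, the cell means enter a block two-way ANOVA
(bin + subject, one observation per cell, so the interaction is the
residual — the classical repeated-measures layout), and each non-reference
bin is contrasted against ZT6 on the residual variance with Sidak (or
Bonferroni) adjustment. With days entering as raw replicates instead, the
null false-positive rate roughly doubled in simulation; the
repeated-measures layout brings it to the nominal 5%.

# Comparison statistics

`two_way_anova()` uses sequential (Type I) sums of squares on balanced
layouts — where they are order-independent and decompose exactly — and
Type II via `car::Anova()` otherwise, with a message. Post hoc adjustments:
Sidak $1-(1-p)^m$, Bonferroni $\min(1, mp)$, Tukey via the studentized
range (`ptukey`; with two groups it reduces exactly to the two-sample
t p-value), and Dunnett's many-to-one comparison via Monte Carlo on the
equicorrelated multivariate t ($\rho = 0.5$ for equal group sizes, $10^6$
draws, fixed internal seed, accurate to about $10^{-3}$; the test suite
cross-checks it against `mvtnorm`). Full repeated-measures covariance
modeling is deliberately out of scope; subject-as-block ANOVA is the
documented approximation.

qPCR quantification is the standard ΔΔCt: ΔCt against a stable reference
(18S rRNA), ΔΔCt against a calibrator sample, relative expression
$2^{-\Delta\Delta Ct}$, so the calibrator is exactly 1 and one cycle less
is exactly 2-fold.

# What the simulators emulate — and what they do not

The generators define the designs every test runs against:

* **Expression** (`expression_sim_config()`): 6 time points (ZT 4…24) × 3
  replicates; rhythmic genes are cosines with mesors uniform in 50–150,
  amplitudes set to a fitted fold of 3, acrophases uniform; arrhythmic
  genes are flat. Noise is additive Gaussian at 10% of each gene's mesor
  by default (multiplicative lognormal is an option). The original
  study's data do not state a noise magnitude; 10% is a documented
  package default chosen as a realistic post-normalization coefficient of
  variation, not a claim about that dataset.
* **Traces** (`trace_sim_config()`): damped cosine plus linear baseline
  drift and Gaussian noise, 10-min sampling, 4–5 days; a treatment is a
  step change of acrophase (`perturbation_phase_shift` > 0 advances the
  peaks).
* **Voiding** (`void_sim_config()`): urine production with a diurnal
  sinusoid peaking in the dark (active) phase; functional capacity a
  sinusoid peaking at ZT6 (mid light phase, default modulation 0.4); a
  void of the current capacity (plus jitter, floored at the 10-µl stain
  detection limit) fires whenever the accumulated volume reaches
  capacity. Volume is conserved to within one capacity by construction.
  Because voids fire at rate production/capacity, the expected volume per
  void in a bin is the production-weighted harmonic mean of capacity —
  `modulation_from_bin_ratio()` inverts exactly that expectation, which
  matters: inverting the plain time-average misestimates a 0.4 modulation
  by ~17%.
* **Calibration** (`simulate_calibration_pairs()`): points on the
  area–volume line spanning 10–800 µl plus optional noise.

None of the generators simulate read-level sequencing, stain-image pixels,
inter-animal variance components beyond the event jitter, or
non-sinusoidal waveforms. Passing tests therefore demonstrate that the
estimators are correct and well-calibrated under the stated models at the
stated noise levels — not that real bladder RNA-seq or aVSOP records meet
those models.

# Numerical choices and problem sizes

Fixed-seed simulation sizes used by the test suite and the acceptance
script, chosen to mirror the emulated designs while keeping the whole
suite under ten seconds: 100-gene matrices (20 rhythmic) for screening;
20-gene paired matrices for offset recovery at offsets 4, 8, 12 h; 96-h
traces for period recovery (22 and 24 h) and 120-h traces for resets
(−10, 0, +12 h), both at 10% noise (robustness spot-checked at 20%);
5 simulated animals × 3 days for micturition; 200 Gaussian null
replicates for the ANOVA type-I check.

Other numerics: acrophases are reduced mod the period; MaxCorr is clipped
to [0, 1] (anti-phase fits cannot occur because the acrophase is free);
ties in argmax peaks and in peak candidates resolve to the earlier time;
quantile-normalization ties share averaged reference values (via
`limma::normalizeQuantiles(ties = TRUE)`); PCA component signs are fixed
by making the largest-magnitude loading positive; a non-positive minimum
time-point mean in `de_filter()` is floored (with a message) so the fold
stays defined.

# Known limitations

* Period is fixed at 24 h in expression screening: a single-cycle design
  cannot resolve period, only phase and amplitude.
* No acrophase confidence intervals: 3 replicates per time point are too
  few for a useful bootstrap; this is an extension point.
* The trace module intentionally omits periodogram methods
  (FFT/Lomb–Scargle) and nonlinear damped-sinusoid fits; the peak-based
  pipeline is transparent and sufficient at the designs above, but a
  spectral method would outperform it on very noisy or very long records.
* `diurnal_rhythm_flag()` approximates repeated measures by a subject
  block; it does not model serial correlation across days.
* Recovered capacity modulation assumes the sinusoidal production and
  capacity forms of the simulator; on real data it is a descriptive
  index, not a parameter estimate.
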