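# circaquant

Quantification of circadian organization for chronobiology experiments:
wheel-running behavior, PER2::LUC-style bioluminescence traces from tissue
explants, and bioluminescence image stacks. The package is aimed at
experiments that ask how central and peripheral clocks stay organized —
for example, how the phase coherence of peripheral tissues changes when
the brain's master clock is disabled, and whether light cycles or
scheduled feeding can restore it.

## What it computes

**Behavior.** For binned wheel-revolution counts: the Sokolove–Bushell
chi-square periodogram

&nbsp;&nbsp;&nbsp;&nbsp;*Q(P) = K·N·Σₕ(Mₕ − M̄)² / Σᵢ(xᵢ − M̄)²*,&nbsp;&nbsp;*Q(P) ~ χ²(B−1)* under white noise,

with the free-running period unscored when no candidate exceeds the
α = 0.001 line; the normalized Fourier power spectrum (area 1 over 0–1
cycles/hr) and the circadian amplitude — the power fraction in the
18–30 hr band [1/30, 1/18] cycles/hr; activity allocations to named daily
windows; the light-masking time course under an ultradian LD 3.5:3.5
cycle, scored per half-hour light bin as 100·L/(L+D) (50% = failure to
mask); and food-anticipatory activity metrics (pre-meal window counts,
half-maximum onset lead, fold change) under a gradual food-restriction
ramp.

**Bioluminescence traces.** Background/gain correction, 24-hr
running-average detrending, 20/192-hr support trimming, and FFT-NLLS
fitting of a damped cosine

&nbsp;&nbsp;&nbsp;&nbsp;*y(t) = c + b·t + A·e^(−t/T)·cos(2π(t−p)/τ)*

seeded from the dominant Fourier component, with the relative amplitude
error RAE ∈ [0, 1] (amplitude confidence halfwidth ÷ amplitude), QC
exclusion at RAE ≥ 0.84 or τ outside 17–31 hr, amplitude normalization
over the 36–60-hr window, second-cycle peak extraction, duplicate-explant
averaging (circular for phases), and phase maps in ZT, CT (predicted
activity onset = CT12) or feeding-time frames.

**Circular statistics.** Mean angle μ, resultant length R, circular
variance V = 1 − R; per-animal cross-tissue variance (frame-invariant);
two-sided Mann–Whitney U (exact by enumeration for small tie-free
samples); Watson–Williams F for mean-angle differences; and a 20,000-
iteration percentile-bootstrap test for differences in circular variance.

**Imaging.** Grid quantification of image stacks (40-µm non-overlapping
squares, intensity-conserving), ranking by total signal, top-200 heat-map
matrices, and per-grid FFT-NLLS fits of the top 50 with period-normalized
phase angles for amplitude and phase-dispersion comparisons.

**Synthetic data.** Seeded generators for all four data types (gated
Poisson activity with masking and food anticipation, damped-cosine traces,
multi-tissue phase panels, cellular image stacks) that export their ground
truth, used throughout the test suite for closed-loop validation.

## Worked example

```r
library(circaquant)

## a rhythmic animal in constant darkness, 28 days
sched <- build_light_schedule(data.frame(pattern = "DD", days = 28))
sim <- simulate_activity(activity_sim_params("control", tau_hr = 23.5,
                                             seed = 42), sched)
pg <- chi2_periodogram(sim$record)
attr(pg, "best_period_hr")            # 23.5
circadian_amplitude(power_spectrum(sim$record))   # 0.772

## a bioluminescence trace: fit, QC, relative amplitude
tr <- simulate_trace(lumi_sim_params(tau_hr = 24.3, phase0_hr = 30, seed = 7),
                     medium_change_hr = 200)
fit <- fft_nlls(prepare_trace(tr$trace))
fit
#> <rhythm_fit> tau = 24.299 hr, first peak = 29.56 hr, A = 300, RAE = 0.017,
#>              damping T = 71.8 hr
relative_amplitude(fit, preprocess_trace(tr$trace))   # 0.332
qc_filter(fit)$retained                               # TRUE

## phase coherence: control vs knockout panels in constant darkness
ctl <- simulate_panel(panel_sim_params(15, "DD", "control", seed = 101))$phases
knockout <- simulate_panel(panel_sim_params(15, "DD", "knockout", seed = 102))$phases
mean(per_animal_variance(ctl)$V)      # 0.043  (tissues tightly phased)
mean(per_animal_variance(knockout)$V)      # 0.428  (internal desynchrony)
mann_whitney(per_animal_variance(ctl)$V, per_animal_variance(knockout)$V)
#> $U 0, $p 3.39e-06

bootstrap_var_diff(hours_to_angle(ctl$phase_hr[ctl$tissue == "liver"]),
                   hours_to_angle(knockout$phase_hr[knockout$tissue == "liver"]),
                   seed = 11)
#> observed -0.734, 95% CI [-0.887, -0.316], significant
```

The numbers read as follows: the periodogram recovers the planted
23.5-hr free-running period; 77% of the control's normalized spectral
power lies in the circadian band; the trace fit recovers the planted
period and peak with an RAE far below the 0.84 exclusion line; and the
knockout panel's per-animal circular variance (0.43 vs 0.04) shows loss
of internal phase coherence, confirmed by the rank test and by the
bootstrap on the liver phase dispersion.

Whole-study runs are driven by YAML configs through `run_behavior()` and
`run_phase_analysis()` (see `inst/scripts/circaquant-cli.R` for a shell
entry point); outputs are tidy CSVs plus a JSON report that records the
seed and every exclusion.

## Vignette

`vignettes/circadian-quantification-methods.Rmd` documents the models and
estimators, all tunable parameters with defaults and units, the synthetic
generators' scope, numerical choices, and known limitations.
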