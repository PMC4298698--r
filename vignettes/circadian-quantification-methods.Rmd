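---
title: "Quantifying circadian organization: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying circadian organization: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaquant)
```

circaquant quantifies circadian organization in three kinds of rodent data:
wheel-running activity records, bioluminescence reporter traces from
cultured tissue explants, and bioluminescence image stacks of whole
explants. This vignette explains the models behind each estimator, the
tunable parameters and their defaults, what the synthetic-data generators
do and do not emulate, and the design decisions taken where the methodology
was genuinely open.

## Time conventions

All schedules live on a continuous hour axis starting at ZT0 (lights-on) of
the reference 12:12 light:dark day; light and dark blocks are half-open
intervals `[start, end)`, so every instant maps to exactly one state.
Circadian time for free-running animals is anchored by activity onset:
a straight line is fitted through the last ten detected onsets, its slope
is the free-running period $\tau$, and the extrapolated onset of the
harvest day is defined as CT12, giving
$CT(t) = (12 + 24\,(t - \text{onset})/\tau) \bmod 24$. For arrhythmic
animals, which have no usable onsets, the anchor accepts the onset series
of a paired rhythmic control. The ten-onset regression window is this
package's choice: long enough to average bin-level onset jitter, short
enough to track a drifting period; nothing downstream depends strongly on
it, and the onset detector's parameters are exposed so sensitivity can be
checked (the test suite does this).

## Wheel-running metrics

**Chi-square periodogram.** For a record of $N$ bins folded at a candidate
period covering $B$ bins, with $K$ complete cycles retained (the incomplete
final fold is dropped),
$$Q_P = \frac{K\,N\sum_h (M_h - \bar M)^2}{\sum_i (x_i - \bar M)^2},$$
where $M_h$ are the $B$ column means of the fold. Under a white-noise null
$Q_P \sim \chi^2_{B-1}$, and a period is significant when $Q_P$ exceeds
the $1-\alpha$ quantile of that distribution ($\alpha = 0.001$ by default,
the convention of the standard actigraphy software). The best period is
the argmax of $Q_P$ among significant periods; when nothing exceeds the
line the record's period is left unscored. Candidate periods are
enumerated at the record's bin resolution, so a 6-min record scans
18--30 hr in 0.1-hr steps. A Monte-Carlo test verifies that the pooled
exceedance under i.i.d. Poisson noise stays near $\alpha$.

**Normalized power spectrum.** The mean-removed record is Fourier
transformed with no taper and no zero padding; the discrete power density
restricted to 0--1 cycles/hr is rescaled so its trapezoidal area is
exactly 1. The circadian amplitude is the integral of this normalized
density over the closed band $[1/30, 1/18]$ cycles/hr (18--30 hr periods),
with linear interpolation at the band edges. Normalization makes the band
fraction insensitive to tapering and padding choices, which is why the
simplest transform is used. For a flat (white-noise) spectrum the band
fraction is the bandwidth itself, $1/18 - 1/30 \approx 0.022$, a useful
arrhythmia baseline.

**Masking score.** Under an ultradian 3.5:3.5 light:dark cycle, to which
mice cannot entrain, acute light suppression is isolated from clock-driven
gating. For each half-hour offset $j$ into the light phase, the score is
$100\,L_j/(L_j + D_j)$ with $L_j$ ($D_j$) the summed counts over the
$j$-th half hour of every light (dark) phase analysed. A score of 50 means
the animal ignores light; 0 means complete suppression. Only light phases
whose paired dark bins fit inside the analysis range are scored, so a
truncated final cycle cannot bias the ratio, and empty bins are reported
as missing rather than zero. The score is invariant to uniform rescaling
of the counts.

**Activity allocations.** Counts are summed over named daily windows
(e.g. daytime, skeleton day vs skeleton night) and expressed as percent of
total activity, so windows partitioning the day sum to 100. For the
skeleton photoperiod 1:10:1:12, "skeleton day" is taken as the 10-hr dark
interval between the two light pulses and "skeleton night" the first 10 hr
of the 12-hr dark interval; which 10 of those 12 hours count as night is
not standardized, so the windows are ordinary arguments.

**Food-anticipatory activity.** Under a feeding schedule, three
quantities are reported: the per-day counts in the 6-hr pre-meal window
(ZT/CT0--6 for the standard ramp ending in a ZT6--10 meal); the onset
lead, defined on the averaged daily profile (6-min bins, smoothed with a
30-min centered moving average to suppress Poisson spikes) as the time
before food at which activity last rises through half of its pre-meal
maximum; and the fold change of mean counts-per-minute in the pre-meal
window relative to the ZT10--24 baseline. A zero baseline flags the fold
change as undefined instead of inventing a value. The gradual
food-restriction ramp itself is constructed from four numbers (first
removal time, first window, daily step, final window); the standard
protocol (18, 12, 2, 4) yields five ramp days ending at a fixed ZT6--10
window:

```{r}
build_fr_ramp(18, 12, 2, 4)
```

## Bioluminescence trace fitting

Raw photomultiplier counts are corrected as `(raw - background) / gain`.
The fitting chain then detrends the full corrected series with a 24-hr
centered running average (edges where the window does not fit are dropped)
and only afterwards applies the support trims: the first 20 hr are
discarded because they carry acute effects of explant preparation, and
data beyond 192 hr or past a medium change are discarded as well.
Detrending *before* trimming is deliberate: the moving average loses 12 hr
at each edge, and taking that loss outside the trimmed window preserves
the earliest -- and for damped rhythms most informative -- 12 hr of the
fitted support. The package exposes both orders (`prepare_trace()` for
detrend-then-trim; `preprocess_trace()` + `detrend_running_average()` for
the reverse), but `prepare_trace()` is the default path: in simulation it
reduces the median period error at low signal-to-noise by roughly 20%.
Note that a centered boxcar passes a sinusoid at the window period almost
untouched while removing constants and linear drift exactly, so the
detrend window (24 hr) and the rhythm period do not conflict; amplitudes
are nevertheless normalized against the *undetrended* corrected signal
(below), accepting the small boxcar attenuation at periods away from
24 hr because groups compared against each other are processed alike.

**FFT-NLLS.** The detrended series is fitted with
$$y(t) = c + b\,t + A\,e^{-t/T}\cos\!\big(2\pi (t - p)/\tau\big)$$
by Levenberg--Marquardt least squares. The fit is seeded from the dominant
discrete-Fourier component with period in 10--40 hr: $\tau$ and phase from
that component, amplitude from its spectral amplitude, and no initial
damping. A single damped component is fitted rather than the
multi-component residual cascade of the original spectral-seeding
approach, because every downstream quantity (period, phase, relative
amplitude, quality control) uses one circadian component per trace; the
damping time constant is bounded below at 12 hr so damping cannot
impersonate a fast trend. Convergence is declared at a relative residual
change below 1e-10 or 500 iterations. If no spectral component in the
10--40-hr band rises above three times the median spectral power, the
trace is flagged non-rhythmic without fitting.

**Relative amplitude error (RAE).** The half-width of the linearized 95%
confidence interval of $A$ (t-quantile times the standard error from the
Gauss--Newton covariance at the optimum) divided by $\hat A$, capped at 1.
RAE 0 is a perfect rhythm; RAE 1 means the amplitude is indistinguishable
from zero. The linearized interval is used instead of a joint
confidence-region search because it is deterministic, fast, and preserves
the 0--1 semantics.

**Quality control.** A fit is excluded when RAE $\ge 0.84$ (background
level) or when $\tau$ falls outside 17--31 hr (24 hr $\pm$ 30%). Both
bounds are exposed in the pipeline configuration and recorded with a
reason code for every exclusion.

**Relative amplitude.** Half the peak-to-trough range of the fitted
oscillation over the 36--60-hr window, divided by the mean *corrected*
signal over the same window. The denominator makes the quantity invariant
to photomultiplier gain and background settings, which is the property the
normalization exists to provide; the specific denominator (window mean of
the corrected signal) is this package's interpretation and is validated by
internal consistency (scale invariance, damping monotonicity) rather than
against any external table.

**Second-cycle peak.** For phase maps, the peak of the second cycle is
read from the corrected series smoothed with a 3-hr centered moving
average: local maxima are indexed from culture start -- including a
first-cycle peak that falls inside the 20-hr trim, since it is visible in
the raw series -- and the second maximum is returned. Peaks must dominate
a 16-hr neighborhood, which rejects noise bumps near troughs. The
smoothed-peak phase and the FFT-NLLS model phase agree within an hour on
clean undamped traces (tested); the smoothed peak is the default for
luminometry phase maps and the model phase for imaging, where traces are
short and noisy and the model pools the whole series.

**Duplicates and phase maps.** Multiple explants of one tissue from one
animal are collapsed before any statistics: peak phases by circular mean
on the 24-hr circle (so 23.5 hr and 0.5 hr average to 0.0, not 12),
scalar quantities arithmetically. Duplicates more than 6 hr apart on the
circle are averaged but flagged discordant -- on a 24-hr circle no two
angles can be more than 12 hr apart, so the flag threshold sits halfway to
that bound. Peak times are then expressed per animal in a common frame:
ZT (hours after lights-on), CT (anchored at predicted onset = CT12), or
feeding time (hours after food onset); angles are always
$2\pi\,\text{hours}/24$, i.e. phases are compared on a common 24-hr
circle, not on each tissue's fitted period.

## Circular statistics

For angles $\theta_i$, with $C = \overline{\cos\theta}$ and
$S = \overline{\sin\theta}$: mean resultant length $R = \sqrt{C^2+S^2}$,
mean angle $\mu = \mathrm{atan2}(S, C)$, circular variance $V = 1 - R$.
$V$ is 0 for perfect clustering, 1 for uniform dispersion, and $\mu$ is
flagged undefined when $R = 0$. Internal phase coherence of an animal is
the $V$ of its six peripheral tissue phases (pituitary, liver, kidney,
heart, lung, spleen); because $V$ ignores rotations, converting a phase
map between reference frames (ZT to CT, say) cannot change it -- a
property the tests assert.

**Mann--Whitney U** compares scalar samples (per-animal $V$, per-grid
amplitudes): exact two-sided p by enumeration of all group assignments
when the pooled sample is at most 12 and tie-free, otherwise the normal
approximation with tie and continuity corrections. Against exhaustive
enumeration at n = 8 + 8 the approximation is accurate to about 0.011 in
the worst case. The test is two-sided throughout.

**Watson--Williams F** compares mean angles of two von Mises samples:
$F = g\,(N-2)(R_1 + R_2 - R)/(N - R_1 - R_2)$ with unnormalized group and
combined resultants, $g = 1 + 3/(8\hat\kappa)$, and $\hat\kappa$ estimated
from the mean within-group resultant. The test assumes concentrated
samples; results are returned with a warning when the mean resultant falls
below 0.45. Simulated type-I error at $\kappa = 2$, n = 15 + 15 sits
within 0.03--0.07 at nominal 0.05 (tested).

**Bootstrap variance difference.** Dispersion differences use a
percentile bootstrap: each of 20,000 iterations resamples both groups with
replacement within group and records $V^*_A - V^*_B$; the 2.5--97.5
percentile interval of these differences is the confidence interval, and
the difference is significant when the interval excludes zero. The
percentile interval (rather than BCa) matches the plain
resampled-difference description of the procedure; the method is a single
function argument away from sensitivity checks. Runs are reproducible
under a caller-supplied seed and the caller's RNG state is restored.
Coverage under an equal-dispersion null at n = 15 per group is about 95%
across replicate datasets (tested at 400 replicates); percentile
intervals are known to undercover slightly at such sample sizes, which the
test band accommodates.

## Imaging grids

Image stacks (frames every 25 min, 10-min exposures treated as
instantaneous samples at the frame midpoint) are reduced to grid series:
the field is tiled with non-overlapping 40-µm squares (a whole number of
pixels; trailing partial rows and columns are dropped, never padded) and
pixel intensities are summed per square per frame, conserving the retained
intensity exactly. Grids are ranked by total summed intensity --
"strongest signal" is otherwise ambiguous; peak and mean rank keys are
available as options -- with deterministic (row, column) tie-breaks. The
heat map takes the top 200 series, detrends each with the 24-hr running
average and min--max scales each row to [0, 1] (the scaling is a display
choice; constant rows are zeroed and flagged). The top 50 series are
fitted with the same FFT-NLLS model (no 20-hr culture trim by default;
imaging starts after explant stabilization), subjected to the same QC, and
a grid failing QC is replaced by the next-ranked grid (configurable, so
dropped-not-replaced analyses are possible). Fitted peak times are
converted to period-normalized phase angles
$2\pi\,(\text{peak} \bmod \tau)/\tau$, so grids with slightly different
periods are compared on a common cycle fraction; amplitude contrasts use
the rank test and dispersion contrasts the bootstrap above.

## Synthetic data: what it emulates, what it does not

The generators are first-class, tested code; every generator is
reproducible under a fixed seed and returns the ground truth it planted.

* **Activity** (`simulate_activity`): per-minute Poisson counts with rate
  $(\text{base} + \text{gate} \cdot \text{night}(t) + \text{faa}(t)) \cdot m(t)$.
  The circadian gate adds activity during subjective night; under
  entrainable LD/LDLD schedules it phase-locks to lights-off (a hard
  daily reset rather than a phase-response model -- sufficient for every
  metric tested here, and a deliberate non-goal to improve), and
  free-runs at $\tau$ otherwise. Knockout mode removes the gate entirely.
  Masking multiplies the rate by $1 - s$ during light, engaging only
  after a configurable onset delay with instantaneous release at dark;
  the delay is modeled as onset-only because a delayed release would
  suppress the paired dark bins and push the first-bin masking score
  above 50%, which is not the phenotype the delay exists to represent.
  The anticipation component rises exponentially over a few hours before
  food and saturates across restriction days from near zero on day 1.
  Defaults (gate 15 counts/min over base 0.5, $\tau$ 23.7 hr, suppression
  0.8) keep daytime activity at a few percent of the total, as in
  rhythmic controls.
* **Traces** (`simulate_trace`): damped cosine plus baseline, linear
  drift, and Gaussian or Poisson noise at 10-min sampling, floored at
  zero, re-expressed through gain/background metadata so the correction
  step is exercised.
* **Panels** (`simulate_panel`): animal-level phases are wrapped normal
  around the condition mean; tissue phases add a per-tissue mean offset
  and wrapped-normal scatter. Wrapped-normal is used rather than von
  Mises because its SD is parameterized directly in hours; calibration
  tests confirm the realized circular SD matches the planted value within
  10% at large n. Condition presets encode the study structure: tight
  phases under light cycles for both genotypes (SD ~1 hr), dispersed and
  damped knockout rhythms in constant darkness (tissue scatter 4 hr,
  amplitude ×0.3), and a feeding preset that locks liver and kidney to a
  feeding-determined phase while heart, lung and spleen stay dispersed.
  Where the underlying studies report only directions, these SDs are
  chosen as plausible magnitudes, and tests assert directions, not the
  magnitudes themselves.
* **Stacks** (`simulate_stack`): cells at uniform random positions with
  Gaussian footprints, damped-cosine intensities with wrapped-normal
  phases, uniform baseline, Poisson shot noise.

None of the generators model phase-response curves, inter-cell coupling,
transcription-level clock dynamics, behavioral feedback on feeding, or
imaging registration drift. Passing tests therefore certify the
*estimators* -- that each statistic recovers what was planted under the
stated noise -- not that real tissues behave like the generators.

## Numerical choices and degenerate inputs

* Levenberg--Marquardt with box constraints ($A \ge 0$, $\tau$ in band,
  damping rate in $[0, 1/12]$); non-convergence and non-rhythmic traces
  return flagged fits, never errors.
* Model peak times are computed in closed form
  ($t = p + \mathrm{atan2}(-1/T,\ \omega)/\omega + k\tau$), so damping's
  slight advance of the peak is handled exactly.
* Moving averages use the nearest odd sample count so a centered window
  reproduces straight lines exactly; edges are dropped, not padded.
* Partial trailing bins (rebinning), cycles (periodogram folds,
  masking), and grid rows/columns are dropped, never padded -- every
  conservation assertion in the tests is over the retained support.
* All-zero records, constant spectra, empty circular samples, zero
  baselines, and missing anchors reject or flag with explicit reasons;
  exclusion logs carry one line per sample per stage.
* Validation problem sizes: recovery grids use 100 seeds per cell on
  172-hr traces; the bootstrap coverage check uses 400 replicate datasets
  at the full 20,000 iterations; periodogram calibration uses 500
  white-noise records at 15-min bins. These sizes give Monte-Carlo errors
  comfortably below the tolerances they guard.

## Known limitations

* The onset detector is threshold-based; records with heavy daytime
  activity relative to their nocturnal bout (beyond ~10% of the maximum
  rate) need adjusted thresholds, and onset-dependent results should be
  checked for robustness to those settings as the test suite does.
* The Watson--Williams test is only trustworthy for concentrated samples;
  for the dispersed knockout panels the bootstrap variance test carries
  the inference, and the F test's warning should be heeded.
* Relative-amplitude values depend on the normalization denominator
  chosen here; they are internally consistent and gain-invariant but not
  calibrated against any external amplitude table.
* The single-component FFT-NLLS underfits traces with strong secondary
  ultradian components; a multi-component residual cascade is a stretch
  goal, off by default.
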