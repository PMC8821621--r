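---
title: "Methods: diel vertical migration from tags and two-frequency acoustics"
author: "mesotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diel vertical migration from tags and two-frequency acoustics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesotrack)
```

This vignette documents the models, numerical choices and design decisions
behind the package, in the order the pipeline runs. All problem sizes quoted
here (40-day deployments, single-day composites, reduced-n simulations in the
tests) are the package's reference study conditions; the same functions run
unchanged on longer series.

## 1. What the synthetic generators emulate

The pipeline is validated against synthetic data because the motivating data
(PSAT archives and survey echograms) are not redistributable. The generators
are first-class, tested code, and their defaults encode the study system:

* a mid-latitude Northeast-Atlantic deployment (52° N, 15° W; 2019 dates)
  sampled every 6 minutes, with an optional duty cycle of 2 days on / 1 day
  off beginning at day 70 — the tags' actual programming;
* an **oceanic regime** with distinct day and night depth distributions and
  crepuscular transitions;
* a **coastal regime** with no diel structure, full use of a shallow water
  column, and sinusoidal yo-yo bouts;
* two-frequency **echograms** containing a stationary deep scattering layer
  and one or two migrating layers with class-specific dB-difference
  signatures.

### Depth process: comonotone mixture transform of an AR(1) copula

Within a diel period, depth samples are generated as
$Z_t = Q_{\text{period}(t)}\!\left(\Phi(u_t)\right)$, where $u_t$ is a
standard-normal AR(1) process with step correlation
$\varphi = \exp(-\Delta t/\tau)$ and $Q$ is the quantile function of the
period's truncated-normal mixture. This construction was chosen over the
more obvious "draw from the mixture and smooth" because it makes every
plateau sample *exactly* mixture-distributed — the marginal statistics that
calibration pins down are reproduced by construction, and the smoothness
parameter $\tau$ can be changed without re-tuning the marginals. The
e-folding time defaults to $\tau = 60$ min; no published value constrains
it, and it only affects the effective sample size of short-series
statistics, not their expectation.

At sunrise and sunset the day and night quantile functions are blended
linearly over a transition window: $Z_t = (1-\alpha_t) Q_{\text{night}}(p_t)
+ \alpha_t Q_{\text{day}}(p_t)$ with $\alpha_t$ ramping 0→1 over
`transitionMinutes` centered on the solar event. Because the blend is
comonotone (one copula draw drives both quantile functions), crepuscular
samples interpolate between the two distributions rather than mixing their
extremes. The default transition is **30 minutes**: a 250–300 m ascent at a
realistic sustained climb rate (~0.15 m s⁻¹) takes about half an hour, and
longer windows measurably smear the day/night marginals away from the
calibrated targets (with 90-minute ramps the night-time 0–150 m occupancy
drops to ≈0.53, outside the 0.60 ± 0.05 band the generator is supposed to
reproduce). Users simulating slower migrators can raise the value
per regime.

### Calibration of the oceanic mixtures

`calibrateDepthMixture()` fits K-component truncated-normal mixtures (on
[0, 800] m) so that *analytic* moments and interval masses match target
statistics; `buildPreset("paper_oceanic")` uses the five published oceanic
marginals — day mean 412 m (sd 150 m), day occupancy 0.60 in 400–600 m and
0.10 in 100–150 m; night mean 174 m (sd 121 m), night occupancy 0.60 in
0–150 m. Two components per diel period satisfy all targets to numerical
precision (day ≈ 0.82·N(471, 86²) + 0.18·N(136, 30²); night ≈
0.59·N(94, 35²) + 0.41·N(286, 112²)). The optimizer is Nelder–Mead from a
fixed set of moment-matched starts, so calibration is deterministic; it
errors, reporting the worst scaled residual, if any target cannot be met
within its tolerance. Truncated-normal moments use the standard closed
forms; Monte-Carlo draws of the returned mixtures are checked against every
target in the tests.

### Echograms

Grids span 24 h × 0–800 m at 6 min × 1 m (800 m covers the deepest printed
shark depth, 730 m). Each layer contributes a Gaussian depth profile in the
*linear* domain with peak `sv38Peak` dB at 38 kHz and `sv38Peak + deltaSv`
at 18 kHz, centered on a diel trajectory: a smoothed square wave with
2-h cosine ramps at sunrise/sunset (echo layers migrate between plateaus
quickly at twilight). Background noise is exponential in the linear domain
with mean at the preset noise floor (−90 dB by default; −∞ disables noise).
All summation happens in linear space; dB is only the output scale. A
zero-noise column therefore integrates exactly to the sum of the analytic
Gaussian integrals — one of the test oracles.

### What the generators do **not** emulate

No bioenergetics, no temperature–depth covariance (the temperature channel
is a fixed thermocline plus noise), no geolocation error, no vessel motion
or beam geometry, no multiple scattering or attenuation. Passing tests
demonstrate that the *analysis* recovers known structure of this idealized
system; they cannot certify behaviour on raw survey data with calibration
drift, bubble sweep-down or false-bottom echoes.

## 2. Tag processing

**Diel labelling.** Geometric sunrise/sunset (solar elevation crossing 0°,
NOAA low-precision algorithm, accurate to ±2 min) at each date's median
track position. A sample is "day" iff sunrise ≤ t < sunset (half-open: the
sunrise instant is day, sunset instant night). Civil twilight is *not*
used; the reference figures mark sunrise and sunset lines.

**Phase segmentation.** The oceanic phase starts at the first sample where
the interpolated seabed exceeds 200 m (a standard shelf-edge convention —
the crossing is described only qualitatively in the source) *and* measured
depth exceeds 250 m (the published trigger, which absorbs geolocation
timing uncertainty). A series that never satisfies the rule is all-coastal
with `oceanicStart = NULL`, not an error. Terminal residency windows with
unreliable positions are excluded by explicit user-supplied windows, not
auto-detected.

**TAD histograms.** 50-m bins over 0–750 m, [lower, upper) with the last
bin closed; deeper samples land in the last bin. The published figures do
not print bin edges; 50 m is the coarsest width for which every named layer
(0–150, 100–150, 400–600 m) is a union of bins. Gap rows never contribute
to any statistic; fractions sum to 1 per non-empty (phase, diel) stratum.

**Depth unit heuristic.** If >50 % of parsed depths exceed 2000, the column
is assumed to be decimeters and rescaled (a common tag-export dialect);
`unit = "m"`/`"dm"` overrides.

## 3. Periodicity

`resampleHourly()` takes hourly means and fills empty hours (duty-cycle
gaps) with a smoothing spline fitted to observed hourly means within ±72 h,
flagging them `imputed`; gaps wider than twice the window stay missing with
a warning. Imputed hours feed the periodicity analyses only — the cyclic
model fits native samples.

`acfPeriodicity()` reports the lag (≥6 h) of the highest local maximum of
the sample ACF (lags to 96 h). Its null matters: the analysis plan named
phase-randomized surrogates, but phase randomization preserves the power
spectrum, of which the ACF is a deterministic function — that null has
essentially no power against periodicity. The default null is therefore
**AR(1) surrogates** matched to the observed lag-1 autocorrelation and
variance, which tests for periodicity *beyond* short-range autocorrelation;
`"shuffle"` (white null) and `"phase"` are available for comparison. With
200 surrogates the significance threshold is the 0.95 quantile of the null
statistic.

`waveletPower()` is a Morlet CWT (ω₀ = 6, the standard trade-off between
time and period resolution; scale resolution 1/12 octave over periods
2–64 h), implemented by the usual FFT method with zero padding. The global
(time-averaged) power spectrum and its peak period are reported alongside
the full time-resolved power, which localizes regime changes. The mother
wavelet and surrogate count are documented defaults, not published values.

## 4. The cyclic depth-by-hour model

`fitHourlyDepthModel()` fits depth on hour of day with a penalized cyclic
cubic spline (k = 5 basis functions, knots evenly spaced on [0, 24] so
f(0) = f(24)), a per-tag random intercept when several tags are supplied
(dropped with a notice for one tag), and an AR(1) residual correlation at
the native sample spacing, via `mgcv::gamm` with REML smoothing-parameter
selection — the standard R engine for exactly this model formula.
Reported quantities:

* **R²** — squared correlation of fitted and observed depths. The source
  table does not define its R²; this definition is the package's choice.
* **ρ** — the AR(1) coefficient from the fitted correlation structure.
* **edf, p** — effective degrees of freedom and the approximate F-type
  p-value of the smooth.
* **SE range** — the min–max *pointwise standard error of the predicted
  curve*. The reference table prints "SE" ranges without defining them;
  this interpretation is flagged as such.

`predictDepthCurve()` returns the population-level curve (marginal to tag
intercepts) with pointwise SEs; periodicity of the basis guarantees equal
endpoint predictions. Parameter recovery (cosine truth, AR(1) noise),
type-I error of the smooth p-value on null series, and endpoint periodicity
are exercised in the tests at reduced problem sizes (3 days at 12-min
sampling for recovery; 200 null series of 240 half-hourly samples).

## 5. Acoustics

**Echo integration.** All cell averaging is in the linear domain
(sv = 10^(Sv/10)); by Jensen's inequality the linear-domain mean is never
below the dB-domain mean, with equality only for constant cells — a tested
invariant. 24-h composites fold absolute time onto time-of-day bins,
averaging multi-day cells linearly; never-observed bins stay masked.

**Classification.** The four ΔSv intervals are implemented half-open,
closed at the upper end — (−14, −3], (−3, 0], (0, 3], (3, 12] — so
boundary cells classify deterministically; the printed tree uses strict
inequalities whose boundaries are measure-zero. Cells with Sv₃₈ below a
−85 dB gate are left unclassified (noise-floor suppression; the source
applies no stated gate). Each classified cell carries its linear 38-kHz
backscatter as weight.

**Kernel densities.** Per class, a binned 2D Gaussian KDE over (time of
day, depth): classified cells are aggregated onto a 0.5 h × 10 m grid and
blurred with a separable kernel, circular in time (period 24 h). Bandwidths
follow Silverman's rule per dimension with the weighted circular sd in
time and the effective sample size (Σw)²/Σw². Weighting by backscatter is
the default (cells sample biomass density, not counts); unweighted mode is
available since the source does not state which was used. "Scaled to 1"
is implemented as max-normalization per class, matching the figure legends.

**Layer detection.** The source identifies layers visually; the detector is
package-designed plumbing with documented, configurable parameters. The
grid is pre-smoothed along time (5-column running mean in the linear
domain, circular for composites) so exponential background noise cannot
seed peaks. Per column, local maxima of the median-smoothed profile at
least 6 dB above the column background (median) are reduced to
Gaussian-moment centers and thicknesses over their half-prominence region.
Columns are linked left-to-right by an *order-preserving* minimal-cost
matching of active-track centers to peak centers — scattering layers merge
rather than cross, so monotone matching is the physically right assignment
— with a 50 m tolerance per column, survival over up to 10 peakless
columns, and a lateness penalty so continuous tracks outrank stale ones
parked on a crossing path. Track fragments are then merged best-first when
one starts where another ends (velocity-extrapolated endpoint within
25 m + 10 m per gap column), with midnight wrap-around. Tracks persisting
≥2 h are kept; a layer is **migrating** when its median day and night
centers differ by more than 100 m (medians resist the few twilight bins
that can be claimed from a neighbouring layer). A layer that genuinely
merges into the stationary DSL by day (as the primary migrating layer
does) may be reported with its daytime track absorbed — exactly what the
echograms show physically.

## 6. Overlap

`overlapIndex()` scores each class by the mean of its max-scaled density
sampled along the depth curve on an hourly grid (bilinear interpolation,
circular in time). The null re-scores `nPerm` transformed curves (uniform
cyclic hour shift; uniform depth offset keeping the curve inside the map);
`p = (1 + #{null ≥ observed}) / (nPerm + 1)`, z standardizes the observed
index against the null. Curves leaving the depth range are clipped with a
warning. Ranking is by index, ties by z then class name. Both the statistic
and the null are package-designed: the source makes the shark–layer
association visually, and this index quantifies that overlay claim. On
coupled simulations (curve generated to track one layer) the tracked
layer's class takes rank 1 in ≥95 % of seeds — a tested property.

## 7. Degenerate inputs and numerical conventions

* Constant depth series: periodicity functions error ("zero variance").
* Empty TAD strata are absent rows, never 0/0.
* Zero-noise echograms contain −∞ dB cells (linear 0); all algebra happens
  in the linear domain, and layer detection treats non-finite cells as
  background.
* Mixture quantile functions invert the CDF on a 2048-point grid except
  for single components, which use the exact closed form (so zero-variance
  regimes produce exact plateaus).
* All generators restore the caller's RNG state; identical preset + seed
  gives bit-identical output.
* Monotone-matching ties in layer linking and ranking ties in the overlap
  are broken deterministically (first match in depth order; alphabetical).

## 8. Known limitations

* The GAMM's between-tag structure is a random intercept only — no random
  smooths, no posterior-simulation intervals.
* Layer detection assumes layers separate by >~50 m outside merge events;
  denser layer stacks need a finer linking tolerance.
* The solar algorithm is not valid inside polar circles (it errors).
* Hourly imputation is a smoothing spline, adequate for duty-cycle gaps up
  to a few days; longer outages are left missing by design.
* The acceptance-grade statistics are demonstrated on 40-day single-tag
  simulations and single-day composites; multi-platform field data will
  add variance the synthetic conditions do not model.
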