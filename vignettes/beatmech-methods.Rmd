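---
title: "Measuring cardiomyocyte mechanics with an AFM cantilever: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cardiomyocyte mechanics with an AFM cantilever: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatmech)
```

## The measurement

A soft AFM cantilever (spring constant around 0.04 N/m) is lowered onto a
spontaneously beating stem-cell-derived cardiomyocyte until the deflection
corresponds to a preset contact force (the *trigger*, 100 pN). The z-piezo is
then locked and the cantilever simply rides the cell: each contraction
deflects it, and multiplying deflection by the spring constant turns the
recording into a force-vs-time *trajectory*, sampled at 2 kHz with a noise
floor around 20 pN. Three quantities characterise each beat: the **force**
(peak height above the resting baseline), the **duration** (full width at
half maximum, FWHM) and the **rate** (reciprocal of the interval to the next
beat).

The approach segment before the trigger is an indentation experiment in its
own right: fitting force versus indentation with a Hertz-family contact
model yields the local Young's modulus, and the contact point itself gives
the local cell height. *Dwell mapping* repeats contact -> indentation -> 10 s
dwell on a grid (10-30 lines of 10-30 points), producing spatial maps of
height, elasticity and contraction force, and — for the statistics — a joint
(beat force, modulus) point per beating grid position.

`beatmech` implements that full pipeline, together with a seeded synthetic
instrument so that every stage can be verified by parameter recovery: the
generators emit ground truth alongside the data, and the test suite asserts
that the analysis recovers it.

## Calibration

The spring constant is estimated from thermal fluctuations of the free
cantilever by equipartition: \(k = k_B T / \langle d^2 \rangle\), with the
variance taken after mean removal (`calibrate_spring_constant()`). The
first-mode correction factor 0.971 — standard for rectangular cantilevers,
because only part of the thermal energy resides in the first flexural mode —
is available as `method = "equipartition_mode1_corrected"` but is not the
default: the measurement protocol this models cites only "the thermal noise
method", so the plain estimator is the faithful default. The temperature
default is 309.15 K (36 °C, the bath temperature of the experiments).

The synthetic thermal series is white Gaussian noise with the equipartition
variance. That is sufficient for testing a variance-based estimator; it does
not model the Lorentzian spectral shape of a real cantilever, so
spectral-fit calibration methods (Sader etc.) are out of scope.

## Beat detection and quantification

`detect_beats()` operates on a lightly smoothed copy of the trajectory
(Gaussian kernel, `smooth_sigma` = 10 ms by default — narrow against beat
widths of 150-300 ms, wide enough to suppress single-sample noise
excursions). The processing chain and the reasoning behind each step:

1. **Baseline.** A rolling lower percentile (10th percentile, 2 s window)
   tracks the diastolic resting tension; beats occupy a minority of each
   window so the low percentile ignores them. Because the p-th percentile of
   noise sits \(z_p \sigma\) below its mean, the baseline is first debiased
   by that known offset; after a provisional detection pass the baseline is
   re-centred on samples away from any detected beat (an asymmetric
   exclusion window, longer after the peak than before it, because the
   relaxation tail outlives the upstroke). Without this second pass the
   percentile statistic mixes noise with beat tails and acquires a bias of a
   fraction of the noise SD — irrelevant for nanonewton beats but a few
   percent of the smallest (0.1 nN) contractions of interest.
2. **Threshold.** `min_height = "auto"` uses
   \(\max(5\hat\sigma_{det}, \text{floor})\), where \(\hat\sigma_{det}\) is a
   robust (MAD-of-first-differences) noise estimate propagated through the
   smoothing kernel, and the floor defaults to 30 pN — 1.5 times the nominal
   20 pN instrument noise and well below the smallest beats of interest. The
   5-sigma rule is deliberately applied to the *smoothed* noise: applied to
   the raw 20 pN it would place the threshold at 100 pN, on top of the
   smallest physiological amplitudes.
3. **Peaks.** Local maxima above threshold, separated by at least
   `min_separation` (0.25 s, i.e. a maximum credible rate of 4 beats/s);
   maxima not separated by a dip below half height are merged, since two
   noise bumps riding one broad contraction dome are a single beat. The peak
   height and time are then refined by a parabolic fit over the top fifth of
   the beat — reading the single maximum sample would carry an upward
   noise-selection bias of order the noise SD.
4. **FWHM.** Half-height crossings located by scanning outward from the
   peak, then refined by a symmetric local line fit: the first sample
   dipping below the level is biased inward under noise (a first-passage
   effect) which the symmetric fit removes. If a crossing is cut off by a
   neighbouring beat's trough, the width is flagged and excluded from width
   summaries. Finally, widths and heights are corrected for the smoothing
   kernel (Gaussian widths add in quadrature; peak area is conserved).
5. **Rate** is assigned to the earlier beat of each pair — the reciprocal of
   the forward interval.

`summarize_beats()` reports mean, SD (n-1), SEM and CV per metric. Both SD
and SEM are always reported because published "±" values of this kind are
ambiguous between the two.

On synthetic trains at 2 kHz with 20 pN noise, these choices recover mean
force to a few tenths of a percent (a few pN), mean rate to well under 1%,
and mean FWHM to about one sample period across amplitudes 0.1-2.5 nN
and rates 0.5-2 beats/s — the test suite asserts exactly this.

## The synthetic beat train

Beats are asymmetric two-sided Gaussians (rise sigma 0.35, decay sigma 0.65
of twice the FWHM-equivalent sigma, preserving the nominal FWHM) — a
stand-in for the fast-upstroke/slow-relaxation twitch shape; a symmetric
Gaussian is available for closed-form tests. Inter-beat intervals,
amplitudes and widths are truncated normals with configurable CVs; noise is
additive white Gaussian (20 pN default); baseline drift (sinusoid + ramp)
defaults to zero, modelling an equilibrated cantilever.

What the generator does *not* emulate: correlated (1/f) instrument noise,
beat-shape variability beyond width/amplitude scaling, arrhythmic interval
structure, or mechanical coupling between neighbouring dwell points. Passing
parameter-recovery tests therefore demonstrates correctness of the
estimators under the stated noise model, not robustness to every pathology
of live-cell recordings.

In recovery sweeps the beat duration is drawn from
\(U(0.15, \min(0.3, 0.3/\text{rate}))\) s: contraction occupies at most
roughly 30% of the cycle, consistent with systolic fractions in
spontaneously beating cardiomyocytes. Trains whose relaxation tails never
return to baseline (duty cycles well above this) leave the resting tension
genuinely unobserved, and *no* baseline estimator can then separate force
from offset; the cap states the regime in which the pipeline's accuracy
claims hold.

## Indentation and the Hertz fit

Three contact models are supported (`hertz_force()`), all with Poisson ratio
0.5 (incompressible cell) by default:

* cone (Sneddon): \(F = \frac{2}{\pi}\tan\alpha\,\frac{E}{1-\nu^2}\,\delta^2\)
* sphere (Hertz): \(F = \frac{4}{3}\sqrt{R}\,\frac{E}{1-\nu^2}\,\delta^{3/2}\)
* pyramid (Bilodeau): \(F = 0.7453\,\tan\alpha\,\frac{E}{1-\nu^2}\,\delta^2\)

with indentation \(\delta = (z - z_c) - (d - d_0)\) correcting the piezo
travel for cantilever bending. The default geometry is a cone of 35°
half-angle, a standard approximation of a silicon-nitride pyramidal probe;
this is the largest unstated choice in protocols of this kind, and since the
fitted modulus scales inversely with \(\tan\alpha\), it is surfaced as an
explicit parameter rather than buried.

`find_contact_point()` fits the piecewise model (flat + Hertz) over a grid
of candidate contact points with continuous refinement; because the model is
linear in \(E\) at fixed \(z_c\), each candidate is scored by closed-form
least squares, making the search a profile-likelihood scan. `fit_hertz()`
then solves for \(E\) in closed form — no iterative optimiser, no starting
values, no convergence failures; the tests cross-check it against an
independent one-dimensional optimiser.

A note on internal consistency of the published scales: at 100 pN and
\(E \approx 300\) Pa, the 35° cone model gives a trigger indentation of
~750 nm, while typical cellular indentation is quoted as 200-500 nm; those
two are reconcilable only for \(E\) near 0.7-4 kPa or a blunter effective
tip. The package reports the value its stated model computes.

Synthetic approach curves solve the force balance \(kd = F(\delta)\)
self-consistently at every z (closed form for the quadratic geometries,
Newton for the sphere), sample 2000 points (2 kHz over a ~1 s approach
sweep), and indent to the greater of the 100 pN trigger depth and 200 nm —
on stiff samples the trigger is reached almost immediately and a fixed
minimum depth keeps the information content of the curve comparable across
the modulus range.

Cell height is the difference between the substrate contact point and the
cell contact point in the same z frame; in assembled dwell maps the deepest
contact among non-beating (glass) points serves as the substrate reference.

## Dwell maps and the healthy / DCM comparison

`analyze_dwell_point()` pairs the indentation fit with the dwell's beat
metrics; a point is *beating* if at least `min_beats = 2` beats are detected
in its 10 s dwell (the protocol never states a minimum, so it is a
configurable threshold, with a low-confidence flag when the dwell is shorter
than two detected periods). Per-point contraction force is the **mean** of
the dwell's beat peak forces (mean/median/max is another unstated choice;
the mean is the default and the events are retained so any summary can be
recomputed). Maps never interpolate; missing values (failed fits,
non-beating points) stay `NA`. `extract_point_set()` yields the joint
(beat force, modulus) observations from beating points only — glass never
leaks in, which the tests assert against the generator's mask.

The synthetic map generator draws each on-cell point's modulus from a
log-normal and its mean beat force from a truncated normal, per mixture
component. Presets encode the two study conditions: a healthy-like cell as a
single population (force 1.35 nN, CV 0.25; log-modulus centred on 296 Pa,
log-SD 0.5) and a DCM-like (dilated cardiomyopathy) cell as an equal mixture
of a near-normal component (0.85 nN, ~280 Pa) and a weak/soft component
(0.25 nN, ~90 Pa), reproducing the bimodal joint distribution reported for
DCM cardiomyocytes at the published scales.

## Statistics

* **Bootstrap** (`bootstrap_ci()`): percentile CIs, B = 10000, explicit
  seed. `transform = "log"` averages log-values and back-transforms, i.e.
  reports the geometric mean — the right convention for right-skewed moduli.
* **Mann-Whitney** (`mann_whitney()`): exact for \(n_1+n_2 \le 16\) without
  ties, midrank normal approximation with tie correction otherwise
  (delegated to `stats::wilcox.test`, validated against full enumeration).
* **Two-sample 2D Kolmogorov-Smirnov** (`ks2d_statistic()`, `ks2d_test()`):
  the Fasano-Franceschini statistic — every observation of each sample in
  turn anchors four quadrants; D is the average of the two samples' maximal
  quadrant-fraction discrepancies. Points on a dividing line count in no
  quadrant. The default p-value is a label permutation (n_perm = 10000,
  \(p = (1 + \#\{D^* \ge D\})/(1 + n_\text{perm})\)), which is defensible at
  any sample size but cannot resolve p below \(1/(1+n_\text{perm})\);
  extremely small published values of this test (e.g. \(10^{-60}\)) can only
  come from an asymptotic formula, so the correlation-corrected Kolmogorov
  tail approximation (Press et al.) is provided as
  `method = "asymptotic"`, clearly labelled as approximate at small n.
* **Hill / EC50** (`fit_hill()`): least squares on
  \(F = \text{base} + (\text{max}-\text{base})/(1 + (EC_{50}/\text{dose})^h)\),
  parameterised in \(\log EC_{50}\) (Levenberg-Marquardt via minpack.lm,
  tight tolerances so noiseless recovery is exact to ~1e-6 relative);
  EC50 CIs by case-resampling bootstrap stratified by dose. Flat responses
  (swing below twice the within-dose noise) are refused as unidentifiable.

## Numerical choices and degenerate inputs

Seeds: every generator takes an explicit integer seed and restores the
caller's RNG state, so identical configs give bit-identical output and
nothing disturbs user code. Quantities are SI throughout (m, N, Pa, s);
file columns carry units in their names (`time_s`, `force_N`,
`deflection_m`, `z_m`). Degenerate inputs fail loudly: constant deflection
series (calibration), flat curves (no contact), all-equal samples
(bandwidth), empty masks, non-uniform time grids, unknown config keys.

Problem sizes in the shipped tests were chosen to exercise the stated
conditions at moderate cost: 120 s trajectories for beat recovery, 60 s
thermal series, 50-seed sweeps for calibration/Hertz/EC50, 15 x 15 dwell
maps, 200 null permutation simulations at n = 30+30 (at n = 20 the
discreteness of D makes the permutation test visibly conservative).

## Known limitations

No viscoelasticity (moduli are effectively "dynamic compliance" when cells
relax under the tip), no adhesion (JKR/DMT), no bottom-effect correction for
thin regions, no lateral force components, no arrhythmia classification, no
vendor file formats. The synthetic data are a physics-grounded stand-in, not
a calibration to any particular instrument's raw recordings.
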