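---
title: "Models and methods: PLR-driven retinal activity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: PLR-driven retinal activity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilflux)
```

# The problem

The pupillary light reflex (PLR) constricts the pupil roughly half a second
after a luminance increase, reaching peak constriction after one to two
seconds. Retinal photon capture is proportional to screen luminance times
pupil area, so the constriction itself is a full-field *negative* luminance
transient: it can drive OFF retinal ganglion cells (RGCs) in the middle of a
constant bright stimulus, suppress ON cells, and — because the PLR is
consensual — couple the two eyes at the level of the retina. `pupilflux`
implements the analysis chain for this phenomenon (pupillometry, calcium
trace processing, axon grouping, binocular modulation and SNR statistics,
functional typing, detection psychophysics) together with a forward
simulator that generates every input the analyses consume. This vignette
documents the models, the tunable parameters, and the numerical choices.

# The generative PLR model

No closed-form pupil model was available for these stimulus regimes, so the
package defines one with the minimal structure that reproduces the measured
behavior. The pupil area of each eye is driven through five stages:

1. **Binocular log drive.** `d(t) = asym(log(L_own/B)) + c_gain *
   asym(log(L_other/B))` with baseline `B` (9.5 lux for the standard
   protocols), consensual gain `c_gain = 0.7` (the consensual response is
   weaker than the direct one; the exact ratio is a free parameter), and a
   0.1 lux floor inside the logarithm so darkness stays finite. `asym()`
   down-weights negative (dilation-driving) excursions by `dilation_gain =
   0.25`: constriction dominates dilation, and without this asymmetry the
   deep troughs of the contrast ramp (0.15 lux, i.e. −4 log units) would
   swamp the drive.
2. **Binocular supralinearity.** While both eyes are simultaneously driven
   and the instantaneous luminance is at or below `boost_knee_lux = 20`,
   the drive is multiplied by `1 + lowcontrast_boost`. This is the
   generator's expression of low-contrast-specific binocular facilitation.
   The default `lowcontrast_boost = 4` was calibrated once so that the full
   pipeline (simulate → ΔF/F → RQI ≥ 0.3 → per-bouton RMI at the third
   contrast-ramp cycle, 12 repeats, 50 boutons) reports a mean RMI of
   ≈ 0.23 over OFF boutons, the facilitation level this model is meant to
   emulate; it was frozen after that calibration.
3. **Saturation.** `g(d) = d/(d + half_sat)`, rescaled so the reference
   high-contrast step (9.5 → 65 lux) has unit drive; `half_sat = 1.2` log
   units. PLR amplitude saturates with flash intensity; this is also what
   makes the *fractional* dimming of a low-contrast step larger than that
   of a high-contrast step, which the detection-task observer relies on.
4. **Neural integration.** Two cascaded first-order stages
   (`tau_drive_s`, 0.35 s mouse / 0.15 s human) low-pass the drive before
   it reaches the iris.
5. **Iris dynamics.** The integrated drive minus a slow adaptation term
   (first-order, solved internally) forms a biphasic target that the
   constriction state tracks with time constant `time_constant_s` (0.35 s
   mouse / 0.20 s human) — but re-dilation speed is capped at
   `dilation_vmax = 0.3` of the full constriction range per second.
   Constriction is parasympathetically fast while dilation is slow; this
   velocity asymmetry, together with the integration stage, is what lets
   the pupil track a 0.55 Hz contrast ramp cycle-by-cycle while only
   constricting gradually under the same ramp at 2 Hz. A first-order
   linear filter alone cannot do this: its gentle rolloff leaves a 2 Hz
   pupil component that dominates the above-0.25 Hz spectrum, whereas the
   measured behavior is a clean dichotomy. With the default parameters the
   FFT tracking fraction is ≈ 75% at 0.55 Hz and ≈ 1.5% at 2 Hz.

The adaptation stage and the transport delay are solved numerically in
`plr_params()` so that the noise-free step response crosses a 2% detection
criterion exactly at `onset_latency_s` and peaks at `time_to_peak_s`
(mouse defaults 0.51 s / 1.74 s; human 0.55 s / 1.18 s), relaxing by
`rebound_amp_frac = 0.3` of the peak during sustained light. Peak
constriction for the reference step is `max_constriction_frac = 0.5` of
baseline area.

Two noise sources are distinguished. Slow physiological fluctuation
(hippus, multiplicative SD 0.01) genuinely modulates retinal illuminance
and is what boutons and the simulated observer experience; white
measurement noise (SD 0.05) contaminates only the recorded trace, as eye
cameras do. Conflating the two would inject frame-rate camera noise into
the simulated retina.

Pharmacology flags clamp the model: atropine fixes the pupil at 1.3×
baseline, carbachol at full constriction (both with zero variance before
measurement noise), and TTX in the ipsilateral eye removes that eye's
contribution to both pupils' drive while leaving the direct pathway
intact.

# Bouton calcium model

All boutons belong to the GCaMP-labelled (contralateral) eye, so their
input is that eye's retinal illuminance `E = L * area/area_0`. The drive is
Weber-scaled, `le = log((E + 0.1)/E_baseline)`; the instantaneous rate is
the rectified derivative (`relu(-d le/dt)` for OFF cells, `relu(+d le/dt)`
for ON), plus `sustained_weight * relu(∓le)` for SUSTAINED kinetics. Rates
are convolved with a peak-normalized double-exponential indicator kernel
(rise 0.1 s, decay 1.0 s). Boutons sharing an axon share the convolved
signal and receive independent Gaussian noise; each bouton also receives
0.9× of a common slow neuropil background, which is emitted separately so
the neuropil-correction step downstream removes something real. An optional
output saturation (`rate_half_sat`) models RGC contrast saturation but is
disabled by default: during the ramp the canonical and pupil-driven drives
overlap in time, and saturating their sum suppresses exactly the binocular
facilitation the generator is meant to express.

The default panel has five types — one transient OFF, two sustained OFF
(differing in gain, tonic weight and decay), one transient ON, one
sustained ON — which the chirp-based clustering pipeline should separate.

# The observer model

The detection-task observer perceives brightness on a log scale. During a
constant step, the PLR erodes the perceived elevation above the adapted
baseline; the observer reports dimming when the *fractional* loss of that
elevation exceeds a threshold (0.45, with 35% relative trial-to-trial
jitter), after a 0.3 s perceptual integration window, 0.15 s persistence,
15% lapses and a 0.35 s motor delay. Because the PLR saturates, a 9.5→12
lux step loses a much larger fraction of its small elevation than a
9.5→65 lux step does, so low-contrast dimming is detected more often —
the qualitative behavior this model exists to reproduce (the simulated
rates, ≈ 88% vs ≈ 22%, are not fitted to any particular dataset).

# Analysis conventions and numerical choices

* **ΔF/F** is computed per trial against the mean of the 2 s before onset
  (removing photobleaching trends); the corrected trace is smoothed with a
  4-frame centered moving mean whose edge windows shrink rather than pad.
* **RQI** uses sample (n−1) variances; the "RQI = 1 for identical trials"
  identity holds either way, and the unbiased form is preferred. Boutons
  are kept if they pass the threshold (default 0.3) under *any* condition,
  so purely binocular responders survive.
* **Kinetics detector.** Onset is the first time the area stays below
  `baseline mean − 2 SD` for ≥ 100 ms, evaluated on the raw trace (a steep
  edge localizes best unsmoothed; a zero-phase low-pass smears it ~0.15 s
  early). Time-to-peak is the argmin evaluated on a 0.5 s moving-mean copy:
  the region around peak constriction is nearly flat, so the raw argmin is
  noise-dominated and biased late, while the smoothed argmin recovers the
  generative 1.74 s to within ±0.02 s on 50-trial averages. Note the
  detector's onset estimate is noise-dependent by construction: with zero
  noise the threshold collapses onto the first measurable movement
  (the transport delay), while at realistic noise it lands at the
  calibrated latency.
* **RMI** integrates the trial-mean ΔF/F rectified at zero over the
  analysis window (On-period for flashes; cycles 2–4 / 7–11 of the ramp
  for the low/high-contrast phases). Without rectification the index is
  unbounded for negative-going traces; rectification keeps it in [−1, 1]
  and is flagged in the result. Boutons whose both AUCs vanish are
  excluded as undefined.
* **Shuffle null.** BOTH/CONTRA labels are shuffled across trials per
  bouton; a normal distribution is fitted to the shuffled RMIs (the
  family is a convention) and facilitation is declared above its 95th
  percentile; one-sided normal p-values are Bonferroni-corrected by the
  axon-group factor (the ceiling of the maximum group size, ≈ 6–7 under
  the default generator).
* **SNR.** The covariance decomposition uses sample covariances over time;
  the noise variance is the mean per-trial variance minus the signal
  variance (the difference written the other way around would be negative
  for any positive-SNR data). SNR is clamped to 0 when the signal-variance
  estimate is negative and reported as the documented cap (`Inf` by
  default, with a `clamped` flag) when the noise variance is zero. The
  peak-wise variant `μ_signal/σ_noise` serves sparse top-responder subsets
  where the covariance estimator is unstable.
* **Summation class** compares the both-eye response to the sum of the two
  monocular responses via a trial-bootstrap band (default 95%): SUPRALINEAR
  when the whole band of the difference lies above zero.
* **Axon grouping** correlates each pair over the union of the two
  boutons' event windows (keeping the pair aligned in time); a bouton with
  no supra-threshold events gets a zero correlation row. Linkage is
  average (the method family was otherwise unspecified); the dendrogram is
  cut at cosine distance 0.85.
* **Clustering** keeps the first two principal components (or a 2-D UMAP
  when configured — chosen manually, not auto-detected) and clusters with
  k-means (25 restarts) or a full-covariance Gaussian mixture initialized
  from k-means; `k` defaults to 5 for contralateral chirp signatures and 2
  for ipsilateral ones. All stochastic steps run under an explicit seed.
* **Pupil preprocessing**: invalid (blink) frames are linearly
  interpolated up to 0.5 s gaps, longer gaps are flagged for trial
  dropping; the standard low-pass is a zero-phase 2nd-order Butterworth at
  1.5 Hz. The FFT tracking fraction mean-detrends, applies a Hann window,
  and integrates a ±0.05 Hz band around the stimulation frequency over the
  power above 0.25 Hz; it is computed on raw (unfiltered) traces so the
  2 Hz measurement is not attenuated by preprocessing.
* **Psychophysics**: detection times are measured from flash onset; the
  primary test across subjects is a paired two-sided t-test of per-subject
  detection rates, with pooled proportions reported alongside. The flash
  default is 3 s. The PFI mirrors the RMI convention,
  `(A_both − A_contra)/(A_both + A_contra)` on constriction amplitudes —
  a package convention, flagged as such.
* **Photon-flux matching** is the linear relative-intensity scaling
  `flux_i = background * step_lux_i / baseline_lux`, rounded to the
  nearest 5 (so a 1500 R*/rod/s background maps the 12 and 20 lux steps to
  1895 and 3160).

# What the simulations do and do not show

The generator emulates the statistical structure the analyses assume:
trial-locked responses with shared-axon correlations, multiplicative pupil
noise, neuropil contamination, photobleaching, pharmacological clamps, and
the two-eye drive geometry. It does not emulate raw imaging movies, eye
videos, receptive-field structure, spiking biophysics, melanopsin/ipRGC
dynamics, or the carbachol-induced change in canonical OFF response shape.
Passing tests therefore demonstrate that the analysis code measures what it
claims to measure on data with known ground truth — not that the generative
model is a complete account of real recordings. Population percentages from
real data (fractions of facilitated boutons, cluster sizes and so on)
depend on the recordings themselves and are checked only qualitatively.

Problem sizes in the test-suite simulations (50 pupil trials for kinetics
recovery; 12 repeats × 50 boutons for the RMI calibration check; 1000
synthetic boutons for the type-I calibration; 60 boutons for axon-grouping
recovery) were chosen so that sampling error is comfortably below each
assertion's tolerance.

# Known limitations

* The PLR model is calibrated to step kinetics and the two ramp
  frequencies; intermediate frequencies interpolate plausibly but are not
  validated.
* The consensual/direct amplitude ratio and the supralinearity knee are
  conventions exposed as parameters, not fitted quantities.
* The observer model is deliberately minimal (no adaptation across trials,
  no criterion drift).
* `rmi()` rectifies at zero, so strongly suppressed (negative-going)
  responses contribute zero area rather than negative area; suppression
  analyses should use `plr_phase_timing()` or work on the unrectified
  traces directly.
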