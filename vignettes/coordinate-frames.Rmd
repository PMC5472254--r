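---
title: "Inferring the coordinate frame of spatial receptive fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the coordinate frame of spatial receptive fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A neuron with a spatial receptive field for sound may encode source position
relative to the *head* (egocentric: its tuning follows the head as it turns)
or relative to the *world* (allocentric: its tuning is anchored to the
arena). With the head fixed at the center of a speaker ring facing forward,
the two hypotheses predict identical tuning curves — the classical mapping
condition cannot distinguish them. `soundframes` implements the full
analysis chain for separating the two frames using data from freely moving
observers, together with a synthetic-data generator that reproduces the
statistical structure the analysis has to cope with.

## Conventions and geometry

All angles are in degrees on the half-open interval (−180, 180],
counter-clockwise positive about the vertical axis (right-hand rule,
consistent with `atan2`); `wrap_angle()` maps −180 to +180 by convention.
Positions are in mm, times in seconds, rates in Hz, speeds in cm/s; units
are embedded in column names (`x_mm`, `t_s`, `speed_cm_s`).

The arena frame has its origin at the arena center and the *front* — the
line of symmetry of the D-shaped arena, toward the 0° speaker — along the
+x axis. With this choice the world-frame sound angle equals the plain
`atan2` angle of the source and no separate display convention is needed; a
positive angle is to the left when facing front. The head frame is defined by
the head midline: the sound angle relative to the head is

θ_HS = wrap(atan2(HS_y, HS_x) − θ_HA),

where HS is the head-to-source vector and θ_HA the head direction in the
arena. Head–source distance is |HS|, and the level at the head assumes
spherical spreading from a source calibrated at the arena center
(0.02 Pa ≡ 60 dB SPL): pressure scales by |AS|/|HS| (origin-to-source over
head-to-source distance), so the level falls by 20·log₁₀(2) ≈ 6.02 dB per
doubling of distance. Head speed is the frame-to-frame displacement divided
by the inter-frame interval, smoothed with a unit-sum 9-point Hann window;
at the series boundary the window is truncated and renormalized, and the
first sample duplicates the first backward difference so the output length
matches the input. The analysis is strictly two-dimensional: head pitch and
roll are assumed negligible whenever both tracking LEDs are visible, which
is the regime in which tracking succeeds at all.

## LED tracking

The tracking module starts downstream of video processing, from per-frame
LED pixel coordinates and intensities. Frames whose LED intensity falls
below a threshold — by default the 1st percentile of the pooled intensity
distribution, configurable because the appropriate cut depends on the
camera — are marked missing; missing runs of at most 10 frames (333 ms at
30 fps) are filled by cubic spline through the neighboring valid samples,
longer or boundary runs are discarded. The image-to-arena mapping
N = T + R·M is a rigid transform estimated by least squares from ≥3 matched
calibration points: rotation from the SVD of the cross-covariance of the
centered point sets (with any reflection corrected to a proper rotation),
translation from the centroids. Head position is the midpoint between the
LEDs and head direction the `atan2` of the posterior→anterior vector.
`render_led_stream()` inverts the whole chain, which gives the test suite a
round-trip oracle that is exact to numerical precision.

## Simulated receptive fields

Egocentric fields are circular Gaussians of the head-frame angle,
P(θ) = a·exp(−(θ−b)²/2c²), with the angular difference wrapped; the
canonical instance (a = 1.044, b = 0°, c = 75.7°) ships as the default
`ego_field()`. Allocentric fields are separable products of
one-dimensional densities over arena x and y, P(x, y) = f(x)·f(y), with
logistic, Gaussian, Laplace or uniform axis families; the canonical
`allo_field()` is logistic with μx = 1000 mm, sx = 400 mm, μy = 0,
sy = 1000 mm. The uniform family uses a half-width parameterization
(support μ ± s), a declared choice where the family's scale convention is
genuinely open. The two canonical fields form a *matched pair*: evaluated
over a speaker ring from the aligned condition their tuning curves agree
with r² > 0.99, which is exactly the ambiguity the pipeline exists to
resolve. Source distance deliberately does not modulate the simulated
fields.

`expected_tuning()` computes the deterministic (noise-free) tuning of a
field under arbitrary behavior: every stimulus epoch is scored by the
field, and epochs are averaged within angular bins of the requested frame.
Binning everywhere uses centers at integer multiples of the bin width, so
the 30° grid between ±90° is congruent across frames and its world-frame
centers coincide with the seven speaker angles. Conditioning on a
head-direction interval reproduces the signature dissociation: conditioned
irrelevant-frame curves shift by the conditioning offset while
relevant-frame curves are invariant.

The *pirouette* trajectory — translation around a 50 mm circle at 30°/step
with simultaneous rotation at 10°/step for 7200 steps — samples every
10°-wide head-direction bin exactly 200 times. Stimulus epochs pair every
step with every speaker of the simulation ring (36 speakers at 10°
intervals, 1000 mm), keeping direction × speaker sampling balanced; under
this behavior irrelevant-frame tuning is flat (residual modulation < 0.005
for both canonical fields).

## Synthetic sessions

`foraging_trajectory()` emulates the behavioral regime the analysis must
survive. Head direction and movement direction are modeled separately, as
in an animal that scans with its head while its body drifts: head direction
follows a Langevin diffusion on the circle with drift −D·κ·sin(θ) and
diffusion √(2D), whose stationary distribution is von Mises centered on the
arena front with concentration κ (`dir_bias_kappa`); the body follows an
independent unbiased heading diffusion at a log-normal AR(1) speed
(default mean 8 cm/s, CV 0.8), with steps that would leave the arena
redirected toward the center. An earlier design that moved the body along
the biased head direction failed structurally: the bias walks the animal
into the front wall, and wall avoidance then destroys the very
head-direction distribution the bias is meant to create.

The default κ = 1.5 was calibrated once so that the squared correlation
between head- and world-frame sound angles across clicks lands near 0.25,
the empirically observed regime for front-biased foraging; at this setting
the circular SD of head direction is ≈ 60°. Clicks have inter-stimulus
intervals uniform on [250, 500] ms, uniformly random speaker identity, and
nominal levels roved uniformly over [54, 60] dB SPL. Spike trains are
inhomogeneous Poisson: background at rate `baseline_rate · exp(speed_beta ·
v(t))` per video frame, plus a click-locked evoked Poisson count with mean
`evoked_gain · P(stimulus) · 0.05 s` placed uniformly within the 50 ms
after onset — the generative kernel is a modeling choice; what the analysis
fixes is the 0–50 ms counting window. Everything is reproducible from a
single integer seed.

What the generator does *not* emulate — and hence what passing tests do not
establish about recordings: acoustics (reverberation, head-related filtering,
interaural cues), spike-timing codes, slow nonstationarities (drift,
adaptation, arousal), overdispersion beyond Poisson, body-versus-head
dissociations, and correlated noise across simultaneously recorded units.

## Screening and the residual-modulation test

Units are screened in two stages, both Poisson GLMs with log link assessed
by χ² analysis of deviance at p ≤ 0.05: (i) responsiveness — window spike
counts (evoked 0–50 ms vs background −50–0 ms) regressed on the period
indicator; (ii) spatial tuning — evoked counts on the 30°-binned head-frame
angle, restricted to the *aligned condition* (head within 5 cm of a point
2.5 cm behind the arena center — the offset approximates the snout-to-head
distance — and within ±15° of the midline), and only attempted when every
angular bin holds ≥5 presentations; units failing the bin-count gate are
reported untestable rather than untuned.

Modulation depth, MD = (max − min)/max × 100 over the ±90° grid, is
scale-invariant and so comparable between firing rates and simulated spike
probabilities. Because behavior is biased, a single-frame unit leaks
modulation into the irrelevant frame; the leak (residual modulation,
MD_irrelevant/MD_relevant) is predicted per session by playing the
session's own clicks and poses through both canonical template fields, and
regressed across sessions on the circular SD of head direction (a
linear-SD fallback is available via `circular_sd = FALSE`). Separate
regressions are kept per frame: the head-frame test uses the
allocentric-template residuals (head irrelevant) and vice versa. A unit's
observed MD ratio in a frame is called significant when it exceeds the
upper *simultaneous prediction bound* for a new observation at the
session's σ — multiplier √(2·F(level; 2, n−2)) (Scheffé / Working–Hotelling)
on the new-observation standard error — the most conservative choice,
minimizing false positives; levels 95% and, Bonferroni-corrected across the
unit population, 1 − 0.05/n (for 92 units, α = 5.43×10⁻⁴). With a finite
number of clicks the residual has a sampling-noise floor even under
perfectly uniform behavior, which the regression absorbs into its
intercept; the deterministic flatness results above hold in the
infinite-sampling (all-epoch) limit.

## Single-trial GLM comparison

`fit_glm_set()` fits four nested Poisson models of evoked counts — constant,
head angle, world angle, both (additive) — and summarizes them as

- model fit: (D_const − D_test)/(D_const − D_full) × 100, the share of
  explainable deviance, bounded in [0, 100] by nesting (asserted on every
  fit), and
- model preference: fit_head − fit_world ∈ [−100, 100], positive for a
  head-frame (egocentric) preference.

The default angle encoding is the first circular harmonic (sin θ, cos θ; two
parameters per frame). A categorical 30°-bin encoding is available, but it
gives the head model 11 degrees of freedom against the world model's 6
(twelve full-circle head bins vs seven speaker angles), so under shuffles
the head frame absorbs a systematically larger share of explainable
deviance and preference is biased positive by construction. Equal
parameter counts make the deviance-share statistics symmetric, which is the
property the frame comparison needs; treating angle as a continuous
circular variable is also the natural reading of a single-trial GLM. AIC
(computed on the deviance scale, D + 2k, where only differences matter)
labels each unit egocentric or allocentric by the better one-frame model,
after excluding units for which neither frame beats the constant model
(analysis of deviance, Bonferroni for the two comparisons); exact AIC ties
break toward the larger model fit and are flagged.

Shuffle controls permute one spatial variable across trials and refit:
shuffling *speaker identity* recomputes both angles from the permuted
speaker and the intact pose, shuffling *head direction* recomputes only the
head-frame angle. Reported are per-frame median fits across shuffles
(medians, because shuffled score distributions are skewed) and the
2.5/97.5 percentile limits of shuffled preference. Two properties deserve
emphasis. First, the shuffled model fit does not drop to zero: the shuffle
retains the unshuffled variable's information by design, and the fit is
renormalized by the (shrunken) explainable deviance, so it is the *change*
in fit that carries the signal — the package's tests assert the
frame-by-unit-type sign pattern of those changes. Second, for egocentric
units, shuffling head direction *increases* the world-frame fit: the
head-frame information destroyed by the shuffle leaves behind exactly the
behaviorally confounded component that the world angle can capture.

`timecourse_fits()` slides a 20 ms counting window at 2 ms steps across
−60…+90 ms around click onset and refits the model set per window; group
timecourses (egocentric vs allocentric populations) are compared by a
cluster-based permutation test: pointwise Welch t statistics thresholded at
the two-sided critical value, contiguous supra-threshold samples scored by
summed t, and the maximum |cluster mass| permutation distribution over
group-label reassignments giving family-wise-corrected cluster p values
(p = (#null ≥ observed + 1)/(n_perm + 1); 500 permutations put the floor at
1/501 ≈ 0.002). The permutation count must resolve the requested α
(n_perm ≥ 1/α − 1 is enforced).

## Distance, speed, and unit identity

The baseline speed–rate function divides spike-triggered speed counts by the
time spent in each speed bin (1 cm/s default width), excluding the 50 ms
after each click from both numerator and denominator; occupancy
normalization makes it flat for homogeneous Poisson spiking regardless of
the speed distribution. An exponential regression rate = r₀·exp(β·v) is fit
by least squares on log rates of positive bins (β = log 2/10 ≈ 0.0693 per
cm/s is a doubling every 10 cm/s). Evoked-rate speed dependence uses a
Poisson GLM of evoked counts on speed at onset with the strict p < 0.001
criterion. Tuning conditioned on distance uses fixed strata 100–200,
200–300, 300–400 mm; speed strata default to 6 quantile bins of the session
speed distribution (quantile rather than fixed-width, since occupancy is
heavily skewed toward low speeds); under-populated strata are flagged and
excluded from group statistics.

Unit identity across sessions is decided from Euclidean distances between
mean waveforms (128 interpolated samples): distances from a test session's
waveform to same-site sessions are compared against the distribution of
distances to spatially separated control sites. Each same-site distance is
tested as a single new observation from the control population
(one-sided prediction-style t test, df = n_control − 1), because the
longest-run logic needs one p value per session; a pooled two-sample Welch
variant is available. P values are Bonferroni-corrected by the number of
sessions at the site, and the tracked run is the longest contiguous
significant run. Single units are flagged by strictly fewer than 1% of
inter-spike intervals under 1 ms.

## Numerical choices and degenerate inputs

- Binning: bin index = round(θ/width); the ±180° boundary bin wraps. Empty
  bins are dropped and counted; curves with no in-range epochs are errors.
- A head pose coincident with a source is a degenerate-geometry error;
  coincident LEDs yield a missing pose for that frame, not an error.
- MD of an all-zero curve, residual modulation with zero relevant MD, and
  model fit with D_const = D_full are undefined and returned as flagged `NA`
  rather than silently zero.
- Preferred-location ties break to the circular mean of tied bin centers and
  are flagged; tuning width counts the contiguous circular run of bins above
  min + 0.5·(max − min) around the peak (the half-height fraction is
  configurable); ERRF width is area under the curve divided by its peak.
- The aligned-subset, screening, and classification stages never silently
  repair inputs: dropped trials, untestable units and excluded sessions are
  counted and reported.

## Problem sizes

The shipped tests and the acceptance script run deterministic field
simulations on the full 7200-step pirouette (259,200 epochs), a 30-session
behavioral ladder (300 s per session) for the residual regression, a
40-unit spiking cohort (4 sessions × ~750 s, ~2000 clicks each) for
end-to-end frame recovery, 25-shuffle controls on a 10-unit subset, and
null calibrations of 300–2000 replicates per screen. These sizes were
chosen to put every Monte-Carlo assertion several binomial standard errors
inside its band on a single CPU in minutes; all of them scale up linearly
via their arguments.

## Known limitations

- The pipeline is two-frame by construction; it does not fit mixed or
  intermediate coordinate frames, gain fields, or body-centered frames.
- Allocentric field *shapes* are never fit to data — the allocentric
  templates are fixed simulation objects, as the inferential logic only
  needs their residual-modulation behavior.
- The level calculation is purely geometric (spherical spreading); room
  acoustics are out of scope.
- Calibration is planar: the 3-D camera pose is reduced to an in-plane
  rotation plus translation, consistent with the planar-head assumption.
- χ² analysis-of-deviance screens are asymptotic; with very low counts
  (≲0.5 expected spikes per window and few trials per bin) their type-I
  error drifts above nominal, which is one reason for the ≥5-per-bin gate.
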