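---
title: "Measuring language lateralization with functional transcranial Doppler: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring language lateralization with functional transcranial Doppler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftcdlat)
```

## The measurement problem

Functional transcranial Doppler ultrasound (fTCD) estimates which cerebral
hemisphere dominates language processing by comparing blood-flow velocity
in the left and right middle cerebral arteries while a participant performs
a language task. The paradigm implemented here is animation description:
each trial is a 12 s silent-watching phase (the baseline), a cue to speak
followed by 10 s of talking (the activation phase), and 8 s of rest, for up
to 30 trials. During activation, flow to the language-dominant hemisphere
rises a few percent relative to the other side; everything else about the
two signals — cardiac pulsation, systemic blood-pressure fluctuations,
probe gain — is either common to both channels or not task-locked, and the
pipeline exists to remove it.

## The processing pipeline

`run_epoch_pipeline()` applies, in this fixed order:

1. **Downsampling to 25 Hz.** A zero-phase Hamming-windowed-sinc low-pass
   (cutoff 0.4 × target rate) precedes rate reduction. Zero phase matters
   because a causal filter would delay the signal and bias the
   peak-latency estimate. Integer rate ratios decimate; non-integer ratios
   linearly interpolate the filtered signal onto the target grid. Marker
   indices are remapped to the nearest output sample, ties rounding down.
2. **Epoch extraction.** One epoch per trial marker, re-indexed so time 0
   is the cue to speak (marker + 12 s). Epochs running past the record are
   rejected (`out_of_bounds`), observer-flagged trials are rejected
   (`annotated_invalid`).
3. **Dropout/spike screening.** Per channel and epoch: samples at or below
   zero or more than 3 SD below the channel mean are dropout; more than
   4 SD above, spiking. Exactly one flagged sample in a channel is repaired
   by substituting the channel mean; two or more anywhere reject the epoch
   (dropout takes precedence in the reported reason). Screening statistics
   use epoch scope by default so a slowly drifting session cannot
   mass-reject trials; session scope is available via
   `epoch_spec(screening_scope = "session")`. The dropout test uses
   "at or below zero" rather than exactly zero to catch negative envelope
   artifacts.
4. **Normalization** of each channel to a mean of exactly 100, making
   units comparable across probes with different gains.
5. **Heart-cycle integration.** Beats are detected on the two-channel mean
   (local maxima, prominence at least 25% of the interquartile range,
   minimum inter-beat interval 0.35 s); each inter-beat interval of each
   channel is replaced by its mean, smoothed by linear interpolation
   between interval midpoints. Plain midpoint interpolation does not
   conserve interval means, so each interval is then re-centred
   additively; conservation holds to 1e-9 and cardiac-band power drops by
   more than 95% on pulsatile test epochs. Epochs in which fewer than two
   beats are detectable (no cardiac structure) skip this stage.
6. **Extreme-value exclusion**: any normalized sample outside the closed
   interval [60, 140] rejects the epoch. The original thresholds are not
   published; these are conventional fTCD bounds and configurable.
7. **Baseline correction**: each channel's mean over 2–12 s post-marker
   (the watching phase minus its first 2 s, which can carry residual
   speech or movement from the previous trial) is subtracted, so the
   left-right difference is zero-mean at the moment the cue arrives.

Stage order matters: because normalization precedes baseline correction, a
pure gain difference between probes cancels exactly (a regression test
pins this), while a DC offset added to the raw signals is absorbed only up
to the multiplicative renormalization. An offset introduced after
normalization is absorbed exactly by baseline correction.

## The laterality index

The grand-average left-minus-right difference across accepted epochs is
searched in the period of interest (POI), 4–14 s after the cue, for its
peak. The LI is the mean difference in a 2 s window centred on that peak,
computed separately per epoch; the session LI is the per-epoch mean, with
standard error and a Student-t 95% confidence interval (z-based CIs
selectable). Classification: `insufficient` below 12 accepted trials;
otherwise `left`/`right` when the CI lies entirely on one side of zero,
`bilateral` when it spans zero.

Two genuinely open choices are resolved as follows:

* **Peak polarity.** "Peak difference" is ambiguous when the difference
  curve is negative. The default takes the maximum of |difference| with
  the sign retained, which makes the method exactly antisymmetric under
  hemisphere exchange (swapping channels negates the LI and mirrors the
  category — a tested invariant). A signed-maximum mode
  (`peak_mode = "signed"`) is provided. Ties break to the earliest
  latency.
* **Degenerate dispersion.** Identical epochs give SE = 0 and a zero-width
  CI; the category is then assigned by the sign of the LI with a warning
  (zero LI with zero SE is bilateral).

The window may extend past the POI (when the peak is within 1 s of a POI
edge) but is clipped at the epoch support. Odd/even split-half LIs use the
parity of the position in the *accepted* sequence, so halves stay balanced
after rejections, and share the overall peak latency.

A caveat the simulation makes visible: because the analysis window is
chosen at the extremum of the observed difference curve, a subject with no
true lateralization tends to get a slightly inflated |LI| — at the
simulator's defaults about 14% of true-zero sessions are called
lateralized, rather than the nominal 5%. This selection effect is a
property of the peak-picking method itself, not of this implementation.

## Cohort statistics

`group_stats` implements the test family used at cohort level from first
principles (base R distribution functions only), with the test suite
checking each against an independent route (`stats::t.test`,
`chisq.test`, `cor.test`, `anova`, expansion loops): Pearson chi-square,
the linear-by-linear (Mantel–Haenszel trend) test `M² = (N−1)r²` on 1 df
with integer scores by default (invariant to affine score changes and
transposition), one- and two-sample t tests (pooled variance by default,
the era-typical convention; Welch selectable), one-way ANOVA,
Mann–Whitney (reported as the first-sample rank sum with a tie-corrected
normal approximation, no continuity correction), Pearson and Spearman
correlations, and the odd/even intraclass correlation. The ICC defaults to
the single-measures, two-way, absolute-agreement form ICC(A,1) with the
McGraw–Wong F-based confidence interval; the consistency form is
selectable, since the form used originally is not stated. P-values are
two-tailed throughout and no multiplicity correction is applied.

Handedness: the Edinburgh Handedness Inventory quotient is
`100(R−L)/(R+L)` over 9 items; the reaching-task quotient is the
proportion of right-hand reaches minus 0.50. Language impairment is
defined as scoring strictly below −1 SD on two or more measures; the
composite language score is the first principal component of the
standardized measures, sign-oriented to track their mean and rescaled to
mean 100, SD 15.

## The population mixture model

`population_model` formalizes the left-brain-bias account: a low-risk
majority lateralizes left with probability ~0.9, a high-risk minority with
probability 0.5 (no bias), and the risk factor — not lateralization
itself — raises the probability of language impairment. The paper gives
the risk-group biases but no impairment rates or prevalence, so the model
adds `p_impair_low = 0.05`, `p_impair_high = 0.5` and `p_risk = 0.2` as
configurable defaults; these are needed to generate case-control tables by
Bayes inversion. Twin concordance under shared risk group and independent
outcomes is `b² + (1−b)²`: exactly 0.5 with no bias, 0.82 at 90:10.
Laterality is binary in the model; the observed bilateral category is
outside its scope.

## What the simulator emulates — and what it does not

`simulate_session()` builds each channel as

```
baseline · (1 + pulsatility · cardiac(t)) + response(t, side)
  + shared drift + independent drift + white noise
```

* **Cardiac**: raised-cosine systolic upstroke with exponential diastolic
  decay, mean 95 bpm with 5 bpm beat-to-beat jitter (child range),
  amplitude 25% of baseline.
* **Response**: zero while watching, raised-cosine rise to a peak 9 s
  after the cue (matching observed peak latencies), decaying to zero by
  the end of rest; per-trial lognormal amplitude jitter (SD 20%).
* **True LI by construction**: the left-right response asymmetry is scaled
  so that the *noise-free pipeline output* equals `true_li` exactly. The
  scale factor comes from a deterministic 3-trial calibration run through
  the real pipeline (cached per parameter set; it consumes no random
  numbers, so seeding stays reproducible).
* **Slow drift**: Ornstein–Uhlenbeck processes (timescale 4 s) — one
  shared between hemispheres (systemic blood-pressure/vasomotion
  fluctuations; it cancels in the difference) and one independent per
  channel. The independent SD, 1.8 normalized units, is the one simulator
  constant derived rather than copied: white noise alone is almost
  entirely removed by heart-cycle integration and window averaging, which
  would make per-epoch LIs implausibly tight. Real sessions of ~24 trials
  show per-subject LI standard errors around 0.6–0.8 and ~20% bilateral
  rates, implying a per-epoch LI SD near 3. With the OU covariance factor
  for (2 s window mean − 10 s baseline mean) at τ = 4 s equal to 1.28,
  `sd = sqrt(8.7 / (2 × 1.28)) ≈ 1.8` delivers that dispersion (measured:
  ≈ 2.7–2.9). This value was fixed from that derivation before any
  acceptance measurement and not revisited.
* **Artifacts**: per trial, dropout (zeros) or spike (2.5 × baseline)
  runs, length expressed at the 25 Hz analysis rate and scaled to the raw
  rate. At a 100 Hz acquisition rate the anti-alias filter smears injected
  single points, as it would real ones; tests that need exact single-point
  semantics therefore simulate directly at 25 Hz, where
  `inject_artifact()` guarantees one-point repairs and multi-point
  rejections.

The simulator does **not** model CO₂ reactivity or autoregulation,
speech-motor artifacts with spectral structure, probe displacement drift,
or any coupling between language ability and signal quality. A green
end-to-end test therefore establishes that the pipeline recovers what this
generative family encodes — not that it is robust to everything a clinic
produces. Pulsatility and drift magnitudes are tuned for pipeline
exercise, not physiological fidelity.

Cohorts (`simulate_cohort()`) assign subjects to the four developmental
subgroups (typical / late bloomer / plateau / persistent SLI) by
largest-remainder rounding, draw true LIs from N(2.2, 3.95) for the
non-impaired and N(−0.2, 3.31) for the impaired subgroups (the printed
group distributions; note these are *observed* dispersions, so simulated
observed SDs land slightly above them), draw six language z-scores by
rejection sampling until they are consistent with the impairment label,
and generate handedness records with right-biased probabilities (EHI item
p = 0.87, reach p = 0.78) matching the printed group means.

## Numerical and calibration notes

* Normalization and baseline-correction post-conditions hold to 1e-9;
  interval conventions are closed for extreme limits and the LI window,
  closed-open for the baseline window.
* The null calibration of the trend test is checked at n = 200 with 5,000
  replicates (rejection rate 0.04–0.06). At small n (e.g. 57) the
  discreteness of the table makes the test mildly conservative (≈ 0.041
  measured) — still within the band, but the larger n isolates the
  asymptotic property being claimed.
* End-to-end LI recovery at defaults gives a mean absolute error of
  ≈ 0.49 normalized units over true LI ∈ {−4…4} (100 seeds each,
  30 trials) — within the 0.5 criterion, but only just; roughly 0.45 of
  it is irreducible sampling error of a 30-trial mean at the simulator's
  realistic per-epoch dispersion, plus the small peak-selection bias near
  zero LI.
* All statistical property tests fix their seeds; thresholds leave about
  three Monte-Carlo standard errors of slack around rates measured over
  larger seed sets during development.

## Known limitations

* The text recording dialect is package-specific; vendor binary formats
  and EDF are out of scope.
* Heart-cycle integration assumes detectable beats; pathological or
  beat-free signals pass through unsmoothed (with the epoch typically
  caught later by screening or extreme-value limits).
* The Mann–Whitney p-value uses the normal approximation; exact small-n
  p-values are not implemented.
* The mixture model treats laterality as binary and cannot generate the
  observed bilateral category; case-control tables from it are 2×2.
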