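---
title: "Methods: postural complexity from trunk accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: postural complexity from trunk accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swaycomplexity)
```

This vignette documents the models, numerical choices, and design decisions
behind `swaycomplexity`, in the spirit of a methods section: what each stage
assumes, which parameters matter, and what the synthetic validation does and
does not demonstrate.

## Measurement model and preprocessing

A trunk-mounted IMU records tri-axial acceleration at 500 Hz during a 60 s
quiet-standing trial. The sensor axes are never perfectly aligned with the
anatomical frame, so a constant fraction of gravity leaks into the horizontal
channels. The pipeline (in `preprocess_trial()`) is, in order:

1. **Downsampling to 100 Hz** (`downsample()`). Decimation is preceded by a
   zero-phase windowed-sinc FIR low-pass with cut-off at the output Nyquist
   rate (60 taps per decimation factor). Naive sample-picking would alias
   broadband sensor noise into the 0.3–10 Hz sway band; with the filter, the
   passband is flat to well under 1% up to 0.8 × the output Nyquist and
   out-of-band power is suppressed below 10⁻⁴.
2. **Central 50 s crop** (`crop_middle()`), yielding exactly 5,000 analysis
   samples and discarding settle-in/out behaviour at the trial edges. The
   crop runs before tilt estimation so that the gravity vector is estimated
   on the same window that is analysed.
3. **Tilt-correction** (`tilt_correct()`). Under the quiet-stance assumption
   the mean acceleration vector estimates gravity in the sensor frame. Two
   sequential rotations — about the ML axis to null the mean AP component,
   then about the updated AP axis to null the mean ML component — realign
   the vertical axis with gravity exactly (the residual horizontal means are
   zero by construction). The rotation order is a convention; for the few
   degrees of tilt seen in practice the alternative order differs only at
   second order in the tilt angles. A warning is raised when the mean vector
   magnitude departs more than 20% from 9.81 m·s⁻² (mounting or unit
   errors), and a zero mean vector is an error.
4. **Band-pass 0.3–10 Hz** (`bandpass()`). A 4th-order Butterworth band-pass
   applied forward–backward (`filtfilt`), i.e. zero-phase with an effective
   8th-order magnitude response, removing respiration-scale drift and
   high-frequency instrument noise. The series is de-meaned and extended by
   odd reflection before filtering so that the forward–backward pass is free
   of edge transients; the residual numerical mean (≈10⁻¹⁶ relative) is
   removed. DC input maps to exactly zero.
5. **Artifact screen** (`artifact_screen()`). The resultant
   `sqrt(ml² + ap²)` of the filtered pair is split into five consecutive
   10 s windows; the trial fails when the largest window SD *strictly
   exceeds* five times the smallest (a ratio of exactly 5.0 passes). The
   screen runs on the filtered signal, consistent with its position after
   filtering in the protocol; since a global rescaling cancels in the ratio,
   only the relative spread matters. In `run_pipeline()` a failing trial
   excludes its whole subject — mirroring how such studies exclude
   participants, not single trials — with the exclusion and reason recorded
   in the run manifest.

## The four measures

All four are computed per axis (ML, AP) on the 5,000-sample signals.

**RMS** (`rms_sway()`): `sqrt(mean(x²))`, reported ×1000 as mm·s⁻². Internal
units are m·s⁻² throughout; the scale factor is configuration
(`unit_scale`).

**Sample entropy** (`sample_entropy()`): −ln(A/B) with template length
`M = 3` and tolerance `r` = 0.07·SD (ML) / 0.06·SD (AP) under the Chebyshev
distance, self-matches excluded. Both template sets run over the `N − M`
positions that have an `(M+1)`-th sample, so `A/B` is a true conditional
probability and a perfectly repeatable signal gives exactly `A = B`, hence
SEn = 0. `A = 0` returns `+Inf` with a warning rather than an arbitrary cap;
downstream statistics treat it as missing. The natural logarithm is used, as
in the estimator's definition, even though the field conventionally labels
the unit "bit"; the label is metadata only. `select_sen_params()` implements
the tolerance/template selection guideline: for each candidate `(M, r)` it
computes the conditional probability `CP = A/B` per record, approximates the
estimator's relative error by the binomial surrogate
`max(σ/CP, σ/(CP·|ln CP|))` with `σ = sqrt(CP(1−CP)/B)`, and picks the
candidate minimising the median across records (ties: smaller `M`, then
larger `r` — the cheaper and better-populated estimate).

**Largest Lyapunov exponent** (`lyapunov_rosenstein()`): delay embedding
(`reconstruct()`) with `m = 4`, `τ = 17` (ML) / `20` (AP) samples; for every
point the Euclidean nearest neighbour outside a Theiler window of
`(m−1)·τ` samples (the attractor's own correlation scale; the protocol is
silent, this is the standard choice); the divergence curve is the mean
log₂ distance of the pairs after `k` steps, pairs dropped when either
trajectory runs off the series or the distance is zero. The exponent is the
least-squares slope over steps 0–75 inclusive (0–0.75 s at 100 Hz),
multiplied by the sampling rate — log base 2 makes the product genuinely
bits·s⁻¹. Neighbours closer than 10⁻⁸·SD are excluded: exactly periodic
test signals sampled commensurately duplicate state-space points to within
rounding error, and log distances of pure rounding noise would otherwise
dominate the curve. On the r = 4 logistic map (analytic exponent ln 2 per
iteration = 1 bit) the estimator lands within 10% using a 0–5 step fit; the
0–75 default is tailored to the 100 Hz sway signals, for which divergence
saturates far more slowly.

For delay and dimension *selection*, `average_mutual_information()` uses a
2-D histogram over `⌈N^(1/3)⌉` equal-width bins. Equal-width (rather than
equiprobable/rank) binning is deliberate: on an exactly periodic record,
rank binning breaks ties by time order and injects lattice noise into the
curve. `first_minimum()` smooths the curve with a 5-point moving average and
requires a lag to be the unique minimum of its ±3-lag neighbourhood —
histogram AMI estimates carry bin-level jitter that would otherwise trigger
spurious first minima; on a 1 Hz sine at 100 Hz the detector lands at the
quarter period (25 samples ± 2) as theory demands. For noise-like curves
with no minimum, the fallback is the first drop below AMI(1)/e, then lag 1
with a warning. `false_nearest_neighbors()` uses the classic two-criterion
test with `Rtol = 15`, `Atol = 2`, and `select_m()` takes the smallest
dimension below 1% false neighbours (noise never drops below it; the largest
tested dimension is returned with a warning).

**Banded DFA** (`dfa()`, `dfa_band_to_scales()`): DFA-1 — integrate the
mean-centered series, remove a per-box linear trend over `floor(N/n)`
non-overlapping boxes from the series start (the trailing remainder is
discarded; with N = 5000 ≫ n ≤ 50 it is negligible), and regress log F(n) on
log n over 10 log-spaced box sizes. The analysis band 2–10 Hz maps to box
sizes by period equivalence `n = fs/f`, i.e. 10–50 samples at 100 Hz,
clipped to the DFA validity range [4, N/4]. Calibration: white noise gives
α ≈ 0.5, spectrally synthesized 1/f noise α ≈ 1.0, integrated white noise
α ≈ 1.5, and synthesized `f^(−β)` noise recovers α ≈ (β+1)/2 within 0.1 for
β ∈ [0.2, 1.8].

## Inference layer

Measure values are transformed by ln(x+1) before inference
(`log1_transform()`); descriptives and figures are anti-logged back.
`mixed_anova_2x2x2()` fits the classical univariate mixed decomposition —
group between subjects, condition and visit within — via `aov()` error
strata: the between effect is tested against subjects-within-groups, each
within effect against its own interaction with subjects-within-groups. With
two levels per factor sphericity holds trivially, so no correction is
applied. Effect sizes are partial η² converted to Cohen's
`f = sqrt(η²/(1−η²))`. The design must be complete; incomplete cells are an
explicit error naming the subjects, not a silent switch to an approximate
fit.

Post-hoc comparisons (`posthoc_report()`) form one BH family per
measure × axis: the group contrast within each condition (independent
pooled t) and the condition contrast within each group (paired t). When no
ANOVA term involving visit reaches α = 0.05, subject values are first pooled
(averaged) across visits; otherwise the comparisons are run per visit. The
family definition is a package convention — the protocol does not specify
the family boundary — and `posthoc_pairwise_bh()` exposes the raw step-up
machinery for any other grouping.

Test–retest reliability uses the one-way random single-measure ICC
(`icc_1_1()`), `(MSB − MSW)/(MSB + MSW)` for two visits, with bands
poor ≤ 0.40 < fair ≤ 0.60 < good ≤ 0.75 < excellent. The reliability gate
(`reliability_gate()`) excludes a measure × axis from inferential testing
when *any* group × condition cell is poor (boundary 0.40 inclusive);
descriptives remain available. `bca_ci()` implements the bias-corrected and
accelerated bootstrap for two-sample mean differences (z₀ from the fraction
of bootstrap statistics below the observed value, acceleration from the
jackknife skewness of both samples, B = 10,000 by default, seeded); in the
symmetric case it reduces to the percentile interval, and simulated coverage
at n = 19 + 19 is nominal within Monte-Carlo error.

## The synthetic cohort generator

`gen_sway_trial()` emulates what the preprocessing stage receives: per
horizontal axis, a colored-noise core (spectral synthesis, amplitude
∝ f^(−β/2)) band-limited to 0.5–10 Hz, mixed with a 0.7 Hz postural
oscillation at variance fraction `periodic_weight`, scaled to an RMS target
(`amp`), embedded in a sensor frame tilted by a few degrees with gravity on
the vertical axis, plus a broadband white sensor noise floor on all three
channels. The core is band-limited so that the 0.3–10 Hz band-pass preserves
the target amplitude (recovery within 10%), while the noise floor is mostly
*removed* by it — the preprocessing demonstrably matters. Defaults
(β = 1.1, periodic weight 0.25, RMS 35/37 mm·s⁻² ML/AP, noise floor
0.012 m·s⁻², 4°/2° tilt) produce measure values in the range reported for
normal-weight adolescents on a firm surface (SEn ≈ 0.9–1.0, LyE ≈ 1,
α ≈ 1.2–1.3, RMS ≈ 35 mm·s⁻²).

Measured knob → measure responses on the processed ML signal (established
during generator design and then frozen): raising β raises α-DFA, lowers
SEn, and raises LyE; raising `periodic_weight` lowers SEn; raising the noise
floor raises SEn and *lowers* the fitted LyE slope (broadband noise inflates
the divergence intercept, not its growth rate). The group effect of the
default `cohort_spec()` therefore rides on β (×1.12) — which alone yields
the full reported overweight signature of lower SEn, higher LyE, higher α —
plus extra repeatability (periodic weight ×1.45) and AP amplitude (×1.25).
The foam condition amplifies amplitude (×1.5 ML, ×1.45 AP) and shifts the
structure knobs the same way (β ×1.07, periodic weight ×1.25). Effects are
multiplicative on knobs, never on measures, so recovery through the pipeline
is a genuine inverse problem. Between-subject variability (log-normal,
SD 0.15 on all knobs, shared across visits) is what makes measures reliable;
per-visit retest jitter (SD 0.05) is what limits ICC — together they land
the ICC grid in the fair-to-excellent range. All randomness derives from a
single seed through named substreams, making cohorts byte-reproducible.

**What the generator does not emulate**: inverted-pendulum dynamics,
foot–foam mechanical coupling, non-stationarity within a trial, or real
sensor error models. Passing the validation suite therefore shows that the
*estimators and inference machinery* behave correctly on signals with
controlled spectral content, regularity, and effect structure — not that the
physiological interpretation of any measure is valid.

## Problem sizes used in validation

The test suite exercises the full 60 s trial length throughout, at reduced
acquisition rates (200 Hz, still an integer multiple of the 100 Hz analysis
rate) and cohort sizes (4–6 subjects per group) for the replicate studies:
type-I calibration of the cohort chain uses 200 replicates of a 5 + 5 null
cohort, power and sign-pattern checks 50 and 5 replicates respectively.
Type-I error and the sign of group mean differences do not depend on the
cohort size; the default `cohort_spec()` remains the full 19 + 19 design at
500 Hz. Oracle-equivalence checks (sample entropy, AMI, FNN, Rosenstein
divergence, mixed-ANOVA F) run brute-force reference implementations on
series of ≤ 500 samples and designs of ≤ 16 subjects, where exhaustive
enumeration is exact and fast.

## Known limitations

* The ANOVA layer requires a complete balanced within-subject design;
  unbalanced data are rejected, not approximated (a mixed-effects
  reformulation is out of scope).
* `+Inf` sample entropies (no extending matches) propagate as missing values
  and can unbalance a design at very tight tolerances.
* The SEn parameter-selection metric uses a binomial variance surrogate for
  the relative error; it reproduces the published parameter choices in kind
  but is an approximation to the original guideline.
* Embedding parameters are fixed per cohort (per the protocol), not adapted
  per subject; `average_mutual_information()`/`false_nearest_neighbors()`
  are provided for cohort-level selection.
* DFA exponents are reliable only for box-size ranges well inside
  [4, N/4]; requesting bands outside the analysable range is an error by
  design.
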