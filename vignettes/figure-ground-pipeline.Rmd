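---
title: "Measuring auditory grouping and its link to speech-in-noise in cochlear-implant listeners"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring auditory grouping and its link to speech-in-noise in cochlear-implant listeners}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfgci)
```

## The measurement chain

Cochlear-implant (CI) listeners vary enormously in how well they understand
speech in noise, and peripheral encoding fidelity — spectral and temporal
resolution — explains only part of that variance. A further candidate is a
central ability: grouping spectrally distributed, temporally coherent sound
elements into one auditory object. `sfgci` implements the full measurement
and inference chain needed to study that question with simulated listeners:

1. **Stimuli** — stochastic figure-ground (SFG) tone clouds, spectral-ripple
   noise and amplitude-modulated complexes (`generate_sfg_stimulus()`,
   `generate_ripple()`, `generate_tm()`, `prepare_oddball_triplet()`);
2. **Adaptive estimation** — a Bayesian updated-maximum-likelihood (UML)
   track over a three-parameter logistic psychometric function
   (`uml_start()`, `uml_update()`, `run_adaptive_session()`);
3. **Scoring** — yes/no d′ and proportion-correct word scoring
   (`dprime_yes_no()`, `score_speech()`);
4. **Device-level control** — an ACE-style n-of-m encoder and an integrated
   current comparison (`ace_encode()`, `compare_current_levels()`);
5. **Cohort inference** — the multiple regression of speech-in-noise accuracy
   on the three psychophysical measures, with normalized coefficients and
   partial correlations (`fit_speech_model()`);
6. **Simulated observers and cohorts** — every component above can be driven
   end to end without human data (`generate_cohort()`,
   `end_to_end_subject()`).

## Stochastic figure-ground stimuli

An SFG stimulus is 4 s of 80 consecutive 50-ms chords. Components live on a
145-point grid spanning 1–8 kHz in 1/48-octave steps; confining all tone
pips to above 1 kHz keeps the stimulus inside the electric-hearing range, so
detection cannot lean on residual low-frequency acoustic hearing. Every
chord contains eight components. On a figure trial, six components are held
at fixed frequencies throughout the second 2 s — the "figure" that can only
be detected by grouping across frequency over time — while the other two are
redrawn at random each chord; on a ground trial all components are redrawn
every chord.

A design decision worth spelling out is *where the half-octave separation
constraint applies*. Six figure components must be pairwise at least half an
octave apart so that figure detection is not confounded with spectral
resolution. Eight components cannot all satisfy that constraint inside a
three-octave grid (they would need 3.5 octaves), so some components must be
unconstrained. We apply an identical within-chord recipe to *every* chord of
*both* trial classes: six components drawn uniformly over the
half-octave-separated sets (a stars-and-bars bijection gives an exact
uniform draw with no rejection loop) plus two unconstrained components. The
two classes then differ **only** in temporal coherence. The alternative —
constraining the figure sextet but building ground chords from eight fully
random components — creates a systematic device-level confound: unconstrained
chords pile more components into single processor channels, and the
compressive n-of-m stage then emits measurably less current for ground
stimuli (rank-sum p ≈ 10⁻²¹ at 60 + 60 stimuli with the encoder below).
Class-identical chord statistics are what make the stimulus-level control
meaningful.

Other synthesis choices: each 50-ms pip gets a 5-ms raised-cosine on/off
flank to limit spectral splatter; pip phases are drawn independently per
chord (no phase continuity of figure components across chords, consistent
with pip-wise synthesis); each stimulus is peak-normalized to the same value
so the class label is not decodable from peak amplitude; and all draws
derive from a single per-stimulus seed, making every generator a pure
function of (spec, seed). Sessions pre-generate `n_trials` unique stimuli,
half per class, in a seed-randomized order.

## Ripple and modulation stimuli

The spectral-ripple stimulus is broadband noise (100 Hz–8 kHz; the band
edges are a package choice, as "broadband" fixes none) whose log-magnitude
spectral envelope is sinusoidal in log-frequency at 1.25 ripples/octave.
`depth_db` is the **peak-to-trough** contrast in dB: white noise is shaped
in the frequency domain by `10^((depth_db/2)·sin(2π·density·oct + φ)/20)`.
A discrimination trial draws one random starting phase per trial, gives it
to both standards, and inverts it (φ + π) for the oddball — the maximally
distinct envelope at equal depth.

The temporal-modulation stimulus sums five equal-amplitude carriers (1515,
2350, 3485, 5045, 6990 Hz), multiplied on modulated intervals by
`1 + m·sin(2π·20t)`. Depth is controlled as `20·log10(m)` dB, so 0 dB is
full modulation and the adaptive track moves over negative values; depths
above 0 dB would clip the envelope and raise an error.

Both are 500 ms with 50-ms linear ramps. Within a three-interval trial the
three sounds are RMS-equalized and then roved independently by a continuous
uniform ±3 dB, removing loudness as a cue; the oddball interval is uniform
over the three positions.

## The UML adaptive procedure

Performance on each oddball task is summarized by the *crossover* of a
three-parameter logistic,

$$p(x) = \gamma + (1-\gamma)\,\frac{1}{1 + e^{-\beta (x - \alpha)}},$$

with threshold/crossover α (dB of depth), slope β (per dB) and guess rate γ
(1/3 at chance for 3AFC). The posterior over (α, β, γ) lives on a fixed
grid — 61 α points over the stimulus domain, 21 log-spaced β points
(0.22–4.5 /dB), 11 γ points (0.15–0.55) — and is updated in log space after
every response; sequential updating is exactly equivalent to a single batch
posterior on the grid, which the tests verify against a brute-force Bayes
oracle.

Priors are configurable and default to α ~ Normal(−18 dB, 10 dB) on the
modulation-depth scale (Normal(15, 10) on the positive ripple-depth scale
preset), log β ~ Normal(0, 0.5), and γ ~ Beta(8, 16) (mean 1/3). The pilot
data that would pin empirical priors are not available, so the defaults are
deliberately wide and proper; with 70 trials the posterior is
likelihood-dominated and recovery is insensitive to moderate prior changes.

Stimulus selection uses the sweet-point rule: for the current
posterior-mean function, the α sweet point minimizes the expected variance
contribution `p(1−p)/(∂p/∂α)²` (for γ = 1/3 it sits near the p ≈ 0.7 point)
and the two β sweet points bracket it; the track cycles mid → low → high,
clamped to the stimulus domain. The estimate reported is the posterior
*mean* (the usual convention when "crossover" is not otherwise qualified).
Lapse rate is not modelled — the function has exactly the three parameters
above — and practice trials, when simulated, are excluded from inference.
With these defaults, 70-trial tracks against logistic observers with
thresholds across −30…−5 dB recover α with |bias| ≈ 0.02 dB and mean
absolute error ≈ 0.4 dB over 200 replicate tracks.

## Scoring

The figure-ground task is yes/no detection, scored as
`d′ = z(hit rate) − z(false-alarm rate)`. Rates are corrected log-linearly —
0.5 added to every cell, 1 to each denominator, *always*, not only at
extreme rates — which keeps d′ finite and continuous; `correction = "clip"`
(1/(2N) clipping) and `"none"` are available for users who prefer other
conventions. Sentence-in-noise performance is the exact ratio of correctly
repeated words to total words. Simulated figure-ground observers are
equal-variance SDT: evidence ~ Normal(d′·[figure], 1) against a criterion,
unbiased at d′/2.

## The electrodogram control

`ace_encode()` implements a canonical ACE-style encoder: 22 channels over
the standard 188–7938 Hz allocation (bins-per-channel
1,1,1,1,1,1,1,1,2,2,2,2,3,3,4,4,5,6,7,8,9,11 × 125 Hz), 8-of-22 maxima per
frame, 900 pulses/s per channel, logarithmic loudness-growth compression
(base 0.0156, saturation 0.5859, ρ = 416.2). Analysis runs at the native
44.1 kHz with a 512-point Hann FFT and 49-sample hop — exactly 900 frames/s
— with channel envelopes as root power sums over each band's bins; FFT
filterbank magnitudes, not per-band Hilbert envelopes, match how such
processors are built. Clinical per-patient maps (T/C levels, rates) are
intentionally out of scope; everything is driven by `ace_config()`.

"Integrated current" is the sum of compressed pulse amplitudes
(dimensionless device units) in a window; the rank-sum comparison between
classes is invariant to sum-versus-mean at equal trial counts. The control
analysis encodes a full 60 + 60 session and compares integrated current in
the 2–4 s window, where the figure can emerge: with class-identical chord
statistics the two distributions coincide, and the two-sided Wilcoxon
rank-sum p is uniform under that null. Tests therefore assert p > 0.05 on a
small fixed set of session seeds rather than "for all seeds", which no
correct implementation could guarantee.

## Cohort inference

The regression layer fits
`azbio ~ 1 + sfg_dprime + ripple_crossover_db + tm_crossover_db` by OLS.
Normalized coefficients are obtained by z-scoring outcome and predictors
before fitting (their SE, t and p come from the standardized fit); the
partial correlation for each predictor is the correlation of the two
residual vectors after residualizing predictor and outcome on the remaining
predictors — a partial, not semi-partial, correlation, and its sign always
matches the coefficient's. Model-level statistics are R², adjusted
R² = 1 − (1−R²)(n−1)/(n−k−1), and F on (k, n−k−1) df. Low-frequency
acoustic thresholds belong in the collinearity screen but not in the model.
All p-values are two-sided with no multiplicity correction, matching
standard practice for a three-predictor confirmatory model.

## The synthetic cohort and what it can show

`generate_cohort()` draws standardized predictors independently and builds
the standardized outcome as `y = 0.292·x₁ − 0.250·x₂ − 0.434·x₃ + ε`. Two
residual-scaling conventions are offered because they cannot hold at once
with independent predictors, where R² equals the sum of squared normalized
coefficients (= 0.336 for these effects):

* `r2 = NULL` — residual variance `1 − Σb²`; the population normalized
  coefficients equal the generating effects exactly (coefficient-faithful);
* `r2 = 0.463` (default) — residual scaled so the population R² hits the
  target; normalized coefficients then inflate by √(R²/Σb²) ≈ 1.17.

A reported (β, R²) pair can only coexist exactly through modest predictor
correlations, which the default generator deliberately excludes (an
optional `predictor_cor` knob exists for robustness checks). Recovery tests
use the coefficient-faithful mode for effects and partial correlations and
the target mode for R².

Natural units are affine back-transforms (d′ 1.5 ± 0.6, ripple crossover
12 ± 4 dB, TM crossover −15 ± 5 dB, word proportion 0.55 ± 0.18, acoustic
threshold 59.4 ± 20.5 dB HL) — plausible ranges chosen once, since the
per-variable marginals behind the published model are not available. Affine
maps leave normalized coefficients untouched; d′ is floored at 0 and the
proportion clipped to [0, 1], each affecting well under 1% of subjects by
construction.

The generator emulates the *linear structure* of a real cohort, not its
full texture: real measures are bounded, heteroscedastic, and mildly
correlated through shared peripheral factors, and real observers drift,
lapse and learn. Passing recovery tests therefore shows the pipeline is
correct and well-calibrated under its stated model — not that the model is
true of any particular clinical population.

## Numerical choices and problem sizes

Likelihoods are clamped to [10⁻¹⁰, 1−10⁻¹⁰] before log-posterior updates;
posterior normalization uses log-sum-exp; sweet points are located on a
401-point domain grid; the frequency-grid length uses a 10⁻⁹ relative guard
against floating-point shortfall at exact octave spans. Session seeds split
into per-trial streams through a deterministic integer map, and every
generator restores the caller's RNG state.

The shipped test and acceptance runs use: 200 replicate UML tracks, 200
d′ sessions per sensitivity level, one to three full 120-stimulus encoded
sessions for the current control, cohorts of n = 4700 for coefficient
recovery, and 500 cohorts of n = 47 for the sign-pattern power check —
sizes at which the Monte-Carlo error is comfortably below each assertion's
tolerance while a full run stays in the minutes range.

## Known limitations

* The encoder is a reference device, not any patient's map; absolute
  current levels are dimensionless.
* No lapse parameter in the psychometric model; severely inattentive
  observers bias thresholds in any such fit.
* The cohort generator's marginals are package constants, not estimates.
* Loudness summation across electrodes, neural-interface variability, and
  free-field calibration are all outside the model.
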