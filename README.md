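# sfgci

Cochlear-implant (CI) listeners differ widely in how well they understand
speech in noise, and spectral/temporal resolution explains only part of that
variance. A central candidate for the rest is *auditory grouping*: binding
temporally coherent components at different frequencies into one object.
`sfgci` is an R implementation of the complete measurement and inference
chain used to study that question — stimulus synthesis, Bayesian adaptive
threshold estimation, signal-detection scoring, a device-level encoding
control, and the cohort regression — runnable end to end against simulated
listeners, with no human data required.

## What the package computes

**Stimuli.** Stochastic figure-ground (SFG) tone clouds: 4-s sequences of
80 × 50-ms chords, eight components per chord drawn from a 145-point
1/48-octave grid over 1–8 kHz; on figure trials six components (pairwise
≥ 0.5 octave apart) stay fixed across the second half. Spectral-ripple
noise (1.25 ripples/octave, depth-controlled, phase-inverted oddball) and
20-Hz amplitude-modulated five-component complexes index spectral and
temporal resolution. Oddball triplets are RMS-equalized and level-roved
±3 dB. Everything is a pure function of (spec, seed) and exports to WAV.

**Adaptive estimation.** Thresholds come from an updated maximum-likelihood
(UML) procedure: a grid posterior over the three-parameter logistic

```
p(x) = gamma + (1 - gamma) / (1 + exp(-beta * (x - alpha)))
```

is refit after every trial and the next stimulus is picked from the
sweet points of the current posterior-mean function. The *crossover*
`alpha` (dB of modulation depth) is the per-subject measure.

**Scoring.** Yes/no sensitivity `d' = z(hit rate) − z(false-alarm rate)`
with log-linear correction, and speech scores as the exact ratio of
correctly repeated words.

**Device-level control.** An ACE-style 22-channel, 8-maxima encoder
(`ace_encode()`) converts stimuli to electrodograms; integrated current in
the 2–4 s window (where a figure can emerge) is compared between classes
with a Wilcoxon rank-sum test to verify current cannot cue trial type.

**Cohort inference.** `fit_speech_model()` fits

```
azbio ~ 1 + sfg_dprime + ripple_crossover_db + tm_crossover_db
```

and reports normalized β (with SE, t, p), partial correlations, R²,
adjusted R² and the overall F — alongside a predictor collinearity screen
and bivariate outcome correlations. `generate_cohort()` builds synthetic
cohorts with independent standardized predictors and normalized effects
(0.292, −0.250, −0.434) on the speech outcome.

## Worked example

```r
library(sfgci)

# one figure trial, synthesized and encoded
s <- generate_sfg_stimulus(sfg_spec(), is_figure = TRUE, seed = 7)
s
#> <sfg_stimulus: figure+ground, 4.00 s, 80 chords, seed 7>
ace_encode(s$waveform)
#> <electrodogram: 28638 pulses on 22 channels over 4.00 s>

# a 70-trial adaptive track against a simulated listener (true alpha -18 dB)
obs <- psychometric_params(alpha = -18, beta = 1, gamma = 1/3)
res <- run_adaptive_session(uml_config(), obs, seed = 4)
res$state
#> <uml: 70/70 trials; posterior mean alpha = -17.76 dB, beta = 1.23 /dB, gamma = 0.342>

# the full synthetic study in one call
fit <- cmd_simulate_study(tempfile("study"), n_subjects = 47, seed = 20)
fit
#> Speech-in-noise regression: azbio_proportion ~ sfg_dprime + ripple_crossover_db + tm_crossover_db (n = 47)
#>                     beta_normalized    se     t        p partial_rho
#> sfg_dprime                    0.442 0.111  3.96 0.000273       0.517
#> ripple_crossover_db          -0.242 0.113 -2.15 0.037100      -0.312
#> tm_crossover_db              -0.435 0.107 -4.06 0.000206      -0.526
#> R^2 = 0.523, adjusted R^2 = 0.489, F(3, 43) = 15.69, p = 4.9e-07
```

The track recovers the simulated listener's threshold to a fraction of a
decibel; the 47-subject fit shows the expected sign pattern — higher
figure-ground sensitivity and lower (better) ripple/modulation thresholds
predict better sentence-in-noise accuracy — with coefficient-level sampling
variation typical of that cohort size.

A command-line wrapper over the same functions is provided:

```sh
Rscript scripts/sfg_pipeline.R synthesize     --out stimuli_dir --seed 1
Rscript scripts/sfg_pipeline.R simulate-study --out study_dir   --seed 1
```

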