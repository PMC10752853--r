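# Spectral-ripple and temporal-modulation oddball stimuli. Ripple noise
# indexes spectral resolution (discriminating the phase of a sinusoidal
# log-frequency spectral envelope at fixed density); the five-component
# amplitude-modulated complex indexes temporal-envelope resolution
# (detecting 20-Hz sinusoidal AM). Both are 500 ms with 50-ms linear ramps,
# RMS-equalized and level-roved within each three-interval trial.

#' Spectral-ripple stimulus specification
#'
#' Broadband noise whose log-magnitude spectral envelope is sinusoidal in
#' log-frequency. `depth_db` is the peak-to-trough spectral contrast in dB;
#' the adaptive track controls it. Density defaults to 1.25 ripples/octave, a
#' low density suited to formant-scale spectral shapes and safe from
#' processor aliasing at high densities.
#'
#' @param density_ripples_per_octave Ripple density (ripples/octave).
#' @param depth_db Peak-to-trough envelope contrast in dB, `>= 0`.
#' @param phase Ripple starting phase in radians.
#' @param band_low_hz,band_high_hz Noise band edges in Hz.
#' @param duration_ms Duration in ms.
#' @param ramp_ms Linear rise/fall in ms.
#' @param sample_rate Sampling rate in Hz.
#' @return A list of class `ripple_spec`.
#' @export
ripple_spec <- function(density_ripples_per_octave = 1.25, depth_db = 20,
                        phase = 0, band_low_hz = 100, band_high_hz = 8000,
                        duration_ms = 500, ramp_ms = 50, sample_rate = 44100) {
  if (depth_db < 0) stop("depth_db must be >= 0", call. = FALSE)
  if (density_ripples_per_octave <= 0) stop("density must be > 0", call. = FALSE)
  structure(
    list(density_ripples_per_octave = density_ripples_per_octave,
         depth_db = depth_db, phase = phase, band_low_hz = band_low_hz,
         band_high_hz = band_high_hz, duration_ms = duration_ms,
         ramp_ms = ramp_ms, sample_rate = sample_rate),
    class = "ripple_spec"
  )
}

#' Synthesize rippled noise
#'
#' White Gaussian noise is shaped in the frequency domain: within the band,
#' the log-magnitude envelope is `(depth_db/2) * sin(2*pi*density*oct +
#' phase)` dB, where `oct` is octaves above the lower band edge (so
#' peak-to-trough contrast equals `depth_db`); energy outside the band is
#' removed. The oddball of a discrimination trial uses `invert_phase = TRUE`
#' (phase + pi), the maximally distinct envelope.
#'
#' @param spec A [ripple_spec()].
#' @param invert_phase Logical; add pi to the ripple phase.
#' @param seed Integer seed for the noise carrier.
#' @return A `waveform`, RMS-scaled and ramped.
#' @export
generate_ripple <- function(spec = ripple_spec(), invert_phase = FALSE, seed) {
  stopifnot(inherits(spec, "ripple_spec"))
  n <- round(spec$sample_rate * spec$duration_ms / 1000)
  phase <- spec$phase + if (invert_phase) pi else 0
  with_seed(seed, {
    x <- stats::rnorm(n)
    X <- stats::fft(x)
    freqs <- (0:(n - 1)) * spec$sample_rate / n
    half <- seq_len(floor(n / 2) + 1)
    f <- freqs[half]
    gain <- numeric(length(half))
    inband <- f >= spec$band_low_hz & f <= spec$band_high_hz
    oct <- log2(pmax(f, 1e-12) / spec$band_low_hz)
    env_db <- (spec$depth_db / 2) *
      sin(2 * pi * spec$density_ripples_per_octave * oct + phase)
    gain[inband] <- 10^(env_db[inband] / 20)
    full_gain <- numeric(n)
    full_gain[half] <- gain
    if (n %% 2 == 0) {
      full_gain[seq(n, floor(n / 2) + 2)] <- gain[2:(floor(n / 2))]
    } else {
      full_gain[seq(n, floor(n / 2) + 2)] <- gain[2:(floor(n / 2) + 1)]
    }
    y <- Re(stats::fft(X * full_gain, inverse = TRUE)) / n
    wf <- waveform(y / max(abs(y)), spec$sample_rate)
    apply_ramp(set_rms(wf), spec$ramp_ms)
  })
}

#' Temporal-modulation stimulus specification
#'
#' Five-component complex (1515, 2350, 3485, 5045, 6990 Hz) sinusoidally
#' amplitude-modulated at 20 Hz. Modulation depth is controlled on a dB
#' scale: `depth_db = 20*log10(m)` for linear depth `m` in (0, 1], so 0 dB is
#' full modulation and more negative values are shallower; the adaptive
#' track operates on this scale.
#'
#' @param carrier_freqs_hz Component frequencies in Hz.
#' @param am_rate_hz Modulation rate in Hz.
#' @param depth_db Modulation depth, dB re full modulation (`<= 0`).
#' @param duration_ms Duration in ms.
#' @param ramp_ms Linear rise/fall in ms.
#' @param sample_rate Sampling rate in Hz.
#' @return A list of class `tm_spec`.
#' @export
tm_spec <- function(carrier_freqs_hz = c(1515, 2350, 3485, 5045, 6990),
                    am_rate_hz = 20, depth_db = 0, duration_ms = 500,
                    ramp_ms = 50, sample_rate = 44100) {
  structure(
    list(carrier_freqs_hz = carrier_freqs_hz, am_rate_hz = am_rate_hz,
         depth_db = depth_db, duration_ms = duration_ms, ramp_ms = ramp_ms,
         sample_rate = sample_rate),
    class = "tm_spec"
  )
}

#' Synthesize the five-component modulated (or unmodulated) complex
#'
#' Deterministic: equal-amplitude cosine-phase carriers, multiplied on
#' modulated intervals by `1 + m*sin(2*pi*am_rate*t)` with
#' `m = 10^(depth_db/20)`.
#'
#' @param spec A [tm_spec()].
#' @param modulated Logical; apply the AM envelope?
#' @return A `waveform`, RMS-scaled and ramped.
#' @export
generate_tm <- function(spec = tm_spec(), modulated = TRUE) {
  stopifnot(inherits(spec, "tm_spec"))
  m <- 10^(spec$depth_db / 20)
  if (modulated && m > 1) {
    stop("modulation depth exceeds full depth (m > 1): envelope would clip",
         call. = FALSE)
  }
  n <- round(spec$sample_rate * spec$duration_ms / 1000)
  t <- (seq_len(n) - 1) / spec$sample_rate
  carrier <- rowSums(sin(outer(t, 2 * pi * spec$carrier_freqs_hz)))
  env <- if (modulated) 1 + m * sin(2 * pi * spec$am_rate_hz * t) else rep(1, n)
  wf <- waveform(carrier * env / max(abs(carrier * env)), spec$sample_rate)
  apply_ramp(set_rms(wf), spec$ramp_ms)
}

#' Assemble one three-interval oddball trial
#'
#' Takes generator closures for the standard and oddball stimuli, equalizes
#' the three intervals to a common RMS, roves each level independently and
#' uniformly over `rove_db` (so loudness is not a reliable cue), and places
#' the oddball in a uniformly random interval.
#'
#' @param standard_gen Function of one integer seed returning a `waveform`.
#' @param oddball_gen Function of one integer seed returning a `waveform`.
#' @param rove_db Length-2 numeric, symmetric about 0 (default `c(-3, 3)`).
#' @param seed Trial seed.
#' @param target_rms Common RMS before roving.
#' @return A list of class `oddball_trial`: `waveforms` (list of 3),
#'   `oddball_index`, `rove_offsets_db`.
#' @export
prepare_oddball_triplet <- function(standard_gen, oddball_gen,
                                    rove_db = c(-3, 3), seed,
                                    target_rms = 0.05) {
  if (length(rove_db) != 2 || abs(rove_db[1] + rove_db[2]) > 1e-12) {
    stop("rove_db must be a symmetric range about 0", call. = FALSE)
  }
  wfs <- list(standard_gen(derive_seed(seed, 1)),
              standard_gen(derive_seed(seed, 2)),
              oddball_gen(derive_seed(seed, 3)))
  wfs <- lapply(wfs, set_rms, target_rms = target_rms)
  with_seed(derive_seed(seed, 4), {
    offsets <- stats::runif(3, rove_db[1], rove_db[2])
    pos <- sample.int(3, 1)
  })
  wfs <- Map(apply_gain_db, wfs, as.list(offsets))
  # place oddball (third element) at position pos, standards in the rest
  out <- vector("list", 3)
  out[[pos]] <- wfs[[3]]
  out[setdiff(1:3, pos)] <- wfs[1:2]
  off_by_pos <- numeric(3)
  off_by_pos[pos] <- offsets[3]
  off_by_pos[setdiff(1:3, pos)] <- offsets[1:2]
  structure(list(waveforms = out, oddball_index = pos,
                 rove_offsets_db = off_by_pos),
            class = "oddball_trial")
}

#' Build a spectral-ripple discrimination trial
#'
#' Draws one random ripple starting phase for the trial; both standards share
#' it and the oddball inverts it. Standard and oddball have the same depth.
#'
#' @param spec A [ripple_spec()]; `depth_db` is the trial's depth.
#' @param seed Trial seed.
#' @param rove_db Level-rove range in dB.
#' @return An `oddball_trial`.
#' @export
ripple_trial <- function(spec = ripple_spec(), seed, rove_db = c(-3, 3)) {
  phase <- with_seed(derive_seed(seed, 99), stats::runif(1, 0, 2 * pi))
  sp <- spec
  sp$phase <- phase
  prepare_oddball_triplet(
    standard_gen = function(s) generate_ripple(sp, invert_phase = FALSE, seed = s),
    oddball_gen  = function(s) generate_ripple(sp, invert_phase = TRUE, seed = s),
    rove_db = rove_db, seed = seed
  )
}

#' Build a temporal-modulation detection trial
#'
#' Either two modulated standards with an unmodulated oddball or the
#' converse, chosen by `modulated_standard`.
#'
#' @param spec A [tm_spec()]; `depth_db` is the trial's depth.
#' @param modulated_standard Logical; are the standards the modulated sounds?
#' @param seed Trial seed.
#' @param rove_db Level-rove range in dB.
#' @return An `oddball_trial`.
#' @export
tm_trial <- function(spec = tm_spec(), modulated_standard = TRUE, seed,
                     rove_db = c(-3, 3)) {
  prepare_oddball_triplet(
    standard_gen = function(s) generate_tm(spec, modulated = modulated_standard),
    oddball_gen  = function(s) generate_tm(spec, modulated = !modulated_standard),
    rove_db = rove_db, seed = seed
  )
}
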