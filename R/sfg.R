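# Stochastic figure-ground (SFG) tone-cloud synthesis. A stimulus is a
# sequence of 50-ms chords, each a sum of equal-amplitude tone pips drawn
# from a fine log-frequency grid; on figure trials a fixed set of components
# repeats in every second-half chord, creating an auditory object that can
# only be detected by grouping across frequency.

#' Geometric frequency grid
#'
#' Builds the log-spaced component grid: frequencies from `low_hz` upward in
#' steps of `1/steps_per_octave` octave, including every step less than or
#' equal to `high_hz`. When the span is an exact number of steps the top
#' frequency is included, e.g. 1-8 kHz at 48 steps/octave gives 145
#' components.
#'
#' @param low_hz Lowest frequency (Hz), positive.
#' @param high_hz Highest frequency (Hz), `>= low_hz`.
#' @param steps_per_octave Number of grid steps per octave, `>= 1`.
#' @return Ascending numeric vector of frequencies in Hz.
#' @examples
#' length(make_frequency_grid(1000, 8000, 48))  # 145
#' @export
make_frequency_grid <- function(low_hz, high_hz, steps_per_octave) {
  if (!is.numeric(low_hz) || !is.numeric(high_hz) || low_hz <= 0 || high_hz <= 0) {
    stop("frequencies must be positive", call. = FALSE)
  }
  if (high_hz < low_hz) stop("high_hz must be >= low_hz", call. = FALSE)
  if (steps_per_octave < 1) stop("steps_per_octave must be >= 1", call. = FALSE)
  n_steps <- floor(steps_per_octave * log2(high_hz / low_hz) + 1e-9)
  low_hz * 2^((0:n_steps) / steps_per_octave)
}

#' Stimulus recipe for the stochastic figure-ground task
#'
#' Defaults give the standard recipe: 4-s stimuli of 80 consecutive 50-ms
#' chords, eight components per chord drawn from a 145-point grid (1-8 kHz,
#' 1/48-octave spacing); on figure trials six components repeat across all 40
#' second-half chords, with pairwise separation of at least half an octave.
#'
#' @param segment_ms Chord duration in ms.
#' @param n_segments_per_half Chords per stimulus half.
#' @param components_per_segment Tone pips per chord.
#' @param n_figure_components Repeating components on figure trials.
#' @param grid_low_hz,grid_high_hz Grid limits in Hz.
#' @param grid_step_octaves Grid spacing as a fraction of an octave.
#' @param min_figure_separation_octaves Minimum pairwise separation of the
#'   figure components, in octaves.
#' @param sample_rate Sampling rate in Hz.
#' @param level_db_spl Nominal presentation level (metadata).
#' @param pip_ramp_ms Raised-cosine on/off ramp per tone pip, in ms.
#' @return A list of class `sfg_spec`.
#' @export
sfg_spec <- function(segment_ms = 50, n_segments_per_half = 40,
                     components_per_segment = 8, n_figure_components = 6,
                     grid_low_hz = 1000, grid_high_hz = 8000,
                     grid_step_octaves = 1 / 48,
                     min_figure_separation_octaves = 0.5,
                     sample_rate = 44100, level_db_spl = 70,
                     pip_ramp_ms = 5) {
  if (n_figure_components > components_per_segment) {
    stop("n_figure_components must not exceed components_per_segment", call. = FALSE)
  }
  if (grid_low_hz >= grid_high_hz) stop("grid_low_hz must be < grid_high_hz", call. = FALSE)
  if (segment_ms <= 0 || n_segments_per_half <= 0) {
    stop("durations and counts must be positive", call. = FALSE)
  }
  structure(
    list(segment_ms = segment_ms, n_segments_per_half = n_segments_per_half,
         components_per_segment = components_per_segment,
         n_figure_components = n_figure_components,
         grid_low_hz = grid_low_hz, grid_high_hz = grid_high_hz,
         grid_step_octaves = grid_step_octaves,
         min_figure_separation_octaves = min_figure_separation_octaves,
         sample_rate = sample_rate, level_db_spl = level_db_spl,
         pip_ramp_ms = pip_ramp_ms),
    class = "sfg_spec"
  )
}

# Uniform draw of n sorted grid indices (1-based) with consecutive index gaps
# >= gap, via the standard stars-and-bars bijection: exactly uniform over the
# feasible sets, no rejection loop.
sample_separated_indices <- function(n_grid, n, gap) {
  slack <- n_grid - (n - 1) * (gap - 1)
  if (slack < n) {
    stop(sprintf(paste0("cannot place %d components with pairwise separation ",
                        ">= %d grid steps on a %d-point grid"),
                 n, gap, n_grid), call. = FALSE)
  }
  j <- sort(sample.int(slack, n))
  j + (seq_len(n) - 1L) * (gap - 1L)
}

# one 50-ms chord: sum of equal-amplitude random-phase tone pips with
# raised-cosine flanks
synthesize_segment <- function(freqs, n_samples, sample_rate, ramp_samples) {
  t <- (seq_len(n_samples) - 1) / sample_rate
  phases <- stats::runif(length(freqs), 0, 2 * pi)
  seg <- sin(outer(t, 2 * pi * freqs) +
             matrix(phases, n_samples, length(freqs), byrow = TRUE))
  rowSums(seg) * raised_cosine_env(n_samples, ramp_samples)
}

#' Synthesize one stochastic figure-ground stimulus
#'
#' Generates the 80-chord tone cloud. Every chord -- in both halves and both
#' trial classes -- is built the same way: `n_figure_components` components
#' drawn with pairwise separation of at least the spec's minimum (uniformly
#' over the feasible sets) plus the remaining components at unconstrained
#' random grid frequencies. On figure trials the separated set is held fixed
#' across all second-half chords, creating the figure; on ground trials it is
#' redrawn every chord. Within-chord spectral statistics are therefore
#' identical between classes by construction -- the classes differ only in
#' temporal coherence -- so neither acoustic energy nor encoded current can
#' cue the trial type. The waveform is peak-normalized to a fixed value so
#' class membership is not decodable from peak amplitude, and the same seed
#' always yields a bit-identical result.
#'
#' @param spec An [sfg_spec()].
#' @param is_figure Logical: does a figure emerge in the second half?
#' @param seed Integer seed fixing all random draws.
#' @return An object of class `sfg_stimulus` with elements `waveform`,
#'   `is_figure`, `figure_frequencies`, `segment_frequencies` and `seed`.
#' @export
generate_sfg_stimulus <- function(spec = sfg_spec(), is_figure, seed) {
  stopifnot(inherits(spec, "sfg_spec"), is.logical(is_figure))
  grid <- make_frequency_grid(spec$grid_low_hz, spec$grid_high_hz,
                              round(1 / spec$grid_step_octaves))
  gap <- ceiling(spec$min_figure_separation_octaves / spec$grid_step_octaves)
  n_seg <- 2L * spec$n_segments_per_half
  n_comp <- spec$components_per_segment
  n_fig <- spec$n_figure_components
  seg_samples <- round(spec$sample_rate * spec$segment_ms / 1000)
  ramp_samples <- round(spec$sample_rate * spec$pip_ramp_ms / 1000)

  with_seed(seed, {
    figure_freqs <- numeric(0)
    if (is_figure) {
      figure_freqs <- grid[sample_separated_indices(length(grid), n_fig, gap)]
    }
    segment_frequencies <- vector("list", n_seg)
    samples <- numeric(n_seg * seg_samples)
    for (k in seq_len(n_seg)) {
      if (is_figure && k > spec$n_segments_per_half) {
        sextet <- figure_freqs
      } else {
        sextet <- grid[sample_separated_indices(length(grid), n_fig, gap)]
      }
      pool <- setdiff(grid, sextet)
      freqs <- c(sextet, sample(pool, n_comp - n_fig))
      segment_frequencies[[k]] <- freqs
      idx <- ((k - 1) * seg_samples + 1):(k * seg_samples)
      samples[idx] <- synthesize_segment(freqs, seg_samples, spec$sample_rate,
                                         ramp_samples)
    }
    wf <- set_peak(waveform(samples, spec$sample_rate, spec$level_db_spl),
                   peak = 0.5)
    structure(
      list(waveform = wf, is_figure = is_figure,
           figure_frequencies = figure_freqs,
           segment_frequencies = segment_frequencies, seed = seed),
      class = "sfg_stimulus"
    )
  })
}

#' @export
print.sfg_stimulus <- function(x, ...) {
  cat(sprintf("<sfg_stimulus: %s, %.2f s, %d chords, seed %d>\n",
              if (x$is_figure) "figure+ground" else "ground-only",
              duration(x$waveform), length(x$segment_frequencies), x$seed))
  invisible(x)
}

#' Generate a balanced figure-ground session
#'
#' Pre-generates `n_trials` unique stimuli, half figure and half ground, in
#' an order randomized by `seed`. Per-trial seeds are split deterministically
#' from the session seed, so the whole session is reproducible.
#'
#' @param spec An [sfg_spec()].
#' @param n_trials Even number of trials (default 120).
#' @param seed Session seed.
#' @return A list of class `sfg_session`: `stimuli` (list of
#'   [generate_sfg_stimulus()] results), `is_figure` (logical vector) and
#'   `seed`.
#' @export
generate_sfg_session <- function(spec = sfg_spec(), n_trials = 120, seed) {
  if (n_trials %% 2 != 0) stop("n_trials must be even", call. = FALSE)
  labels <- rep(c(TRUE, FALSE), each = n_trials / 2)
  order <- with_seed(derive_seed(seed, 0), sample.int(n_trials))
  labels <- labels[order]
  stimuli <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    stimuli[[i]] <- generate_sfg_stimulus(spec, labels[i], derive_seed(seed, i))
  }
  structure(list(stimuli = stimuli, is_figure = labels, seed = seed),
            class = "sfg_session")
}

#' @export
print.sfg_session <- function(x, ...) {
  cat(sprintf("<sfg_session: %d trials (%d figure / %d ground), seed %d>\n",
              length(x$stimuli), sum(x$is_figure), sum(!x$is_figure), x$seed))
  invisible(x)
}
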