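# ACE-style (n-of-m) cochlear-implant encoder. A short-time FFT filterbank
# produces 22 channel envelopes per analysis frame; the 8 largest are kept,
# compressed with a logarithmic loudness-growth function, and emitted as a
# pulse train. Used here for the stimulus-level control: integrated current
# in the window where a figure can emerge must not differ between
# ground-only and figure+ground stimuli.

# Standard 22-channel frequency-allocation table (Hz band edges): bands of
# 1,1,...,11 bins of 125 Hz starting at 187.5 Hz, spanning ~188-7938 Hz.
default_band_edges <- function() {
  bins <- c(1, 1, 1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 4, 4, 5, 6, 7, 8, 9, 11)
  187.5 + 125 * cumsum(c(0, bins))
}

#' ACE encoder configuration
#'
#' Canonical reference device: 22 channels, 8-of-22 maxima selection,
#' 900 pulses/s per channel, Cochlear-style frequency allocation over
#' ~188-7938 Hz, logarithmic loudness-growth compression. All parameters are
#' configurable; clinical per-patient maps are out of scope.
#'
#' @param n_channels Number of electrode channels.
#' @param n_maxima Channels stimulated per frame (n-of-m).
#' @param channel_rate_pps Per-channel stimulation rate (pulses/s); also the
#'   analysis frame rate.
#' @param band_edges_hz Vector of `n_channels + 1` ascending band edges (Hz).
#' @param fft_size Analysis FFT length in samples (Hann window).
#' @param base_level Envelope at/below which no pulse is emitted (full-scale
#'   units).
#' @param sat_level Envelope at which the compressed amplitude saturates.
#' @param lgf_rho Loudness-growth-function steepness.
#' @return A list of class `ace_config`.
#' @export
ace_config <- function(n_channels = 22, n_maxima = 8, channel_rate_pps = 900,
                       band_edges_hz = default_band_edges(), fft_size = 512,
                       base_level = 0.0156, sat_level = 0.5859,
                       lgf_rho = 416.2) {
  if (n_maxima > n_channels) stop("n_maxima must be <= n_channels", call. = FALSE)
  if (length(band_edges_hz) != n_channels + 1 || is.unsorted(band_edges_hz)) {
    stop("band_edges_hz must be n_channels + 1 ascending values", call. = FALSE)
  }
  if (base_level >= sat_level) stop("base_level must be < sat_level", call. = FALSE)
  structure(
    list(n_channels = n_channels, n_maxima = n_maxima,
         channel_rate_pps = channel_rate_pps, band_edges_hz = band_edges_hz,
         fft_size = fft_size, base_level = base_level, sat_level = sat_level,
         lgf_rho = lgf_rho),
    class = "ace_config"
  )
}

# logarithmic loudness-growth function mapping envelope to [0, 1]
lgf_compress <- function(env, config) {
  x <- pmin(pmax(env, config$base_level), config$sat_level)
  log(1 + config$lgf_rho * (x - config$base_level) /
        (config$sat_level - config$base_level)) / log(1 + config$lgf_rho)
}

#' Encode a waveform as an electrodogram
#'
#' Short-time FFT filterbank (Hann window) at the per-channel stimulation
#' rate: per frame, channel envelopes are root-power sums of FFT-bin
#' magnitudes within each band, the `n_maxima` largest are selected,
#' compressed with the loudness-growth function, and emitted as pulses
#' (envelopes at or below the base level produce none). Deterministic.
#'
#' @param x A `waveform`; its sample rate must be at least twice the top
#'   band edge.
#' @param config An [ace_config()].
#' @return An object of class `electrodogram` with vectors `pulse_times`
#'   (s, non-decreasing), `pulse_channels` (1..n_channels) and
#'   `pulse_amplitudes` (compressed device units in `(0, 1]`), plus the
#'   config and source duration.
#' @export
ace_encode <- function(x, config = ace_config()) {
  stopifnot(inherits(x, "waveform"), inherits(config, "ace_config"))
  fs <- x$sample_rate
  if (fs < 2 * max(config$band_edges_hz)) {
    stop("sample rate must be at least twice the top band edge", call. = FALSE)
  }
  N <- config$fft_size
  hop <- max(1L, round(fs / config$channel_rate_pps))
  s <- x$samples
  if (length(s) < N) s <- c(s, numeric(N - length(s)))
  starts <- seq(1L, length(s) - N + 1L, by = hop)
  win <- 0.5 * (1 - cos(2 * pi * (0:(N - 1)) / (N - 1)))
  frames <- vapply(starts, function(i) s[i:(i + N - 1)] * win, numeric(N))
  spec <- stats::mvfft(frames)[seq_len(N / 2 + 1), , drop = FALSE]
  power <- Mod(spec)^2
  bin_freqs <- (0:(N / 2)) * fs / N
  bin_channel <- findInterval(bin_freqs, config$band_edges_hz,
                              rightmost.closed = TRUE)
  keep <- bin_channel >= 1 & bin_channel <= config$n_channels
  # channel envelope: root power sum over the band's bins, scaled so a
  # full-scale sine gives an envelope near 1
  chan_power <- rowsum(power[keep, , drop = FALSE], bin_channel[keep])
  env <- sqrt(chan_power) * (2 / sum(win))
  present <- as.integer(rownames(chan_power))
  envelopes <- matrix(0, config$n_channels, ncol(env))
  envelopes[present, ] <- env

  times <- (starts - 1 + N / 2) / fs
  # n-of-m selection per frame, vectorized: rank envelopes within each frame
  # (column), keep the n_maxima largest that exceed the base level
  nf <- ncol(envelopes)
  rank_in_frame <- matrix(0L, nrow(envelopes), nf)
  ord <- apply(envelopes, 2, order, decreasing = TRUE)
  rank_in_frame[cbind(as.vector(ord),
                      rep(seq_len(nf), each = nrow(envelopes)))] <-
    rep(seq_len(nrow(envelopes)), nf)
  keep_pulse <- rank_in_frame <= config$n_maxima &
    envelopes > config$base_level
  idx <- which(keep_pulse, arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  pulse_times <- times[idx[, 2]]
  pulse_channels <- as.integer(idx[, 1])
  pulse_amplitudes <- lgf_compress(envelopes[idx], config)
  structure(
    list(pulse_times = pulse_times, pulse_channels = pulse_channels,
         pulse_amplitudes = pulse_amplitudes, config = config,
         duration_s = length(x$samples) / fs),
    class = "electrodogram"
  )
}

#' @export
print.electrodogram <- function(x, ...) {
  cat(sprintf("<electrodogram: %d pulses on %d channels over %.2f s>\n",
              length(x$pulse_times), x$config$n_channels, x$duration_s))
  invisible(x)
}

#' @export
as.data.frame.electrodogram <- function(x, ...) {
  data.frame(time_s = x$pulse_times, channel = x$pulse_channels,
             amplitude = x$pulse_amplitudes)
}

#' Raster plot of an electrodogram
#'
#' @param x An `electrodogram`.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.electrodogram <- function(x, ...) {
  graphics::plot(x$pulse_times, x$pulse_channels, pch = "|",
                 cex = 0.4 + 0.6 * x$pulse_amplitudes,
                 xlab = "Time (s)", ylab = "Channel",
                 ylim = c(1, x$config$n_channels), ...)
  invisible(x)
}

#' Integrated current in a time window
#'
#' Sum of compressed pulse amplitudes with pulse time in `[t0, t1)`
#' (dimensionless device units).
#'
#' @param e An `electrodogram`.
#' @param t0,t1 Window start and end in seconds, `t0 < t1`.
#' @return Non-negative sum of pulse amplitudes.
#' @export
integrated_current <- function(e, t0, t1) {
  stopifnot(inherits(e, "electrodogram"))
  if (t0 >= t1) stop("t0 must be < t1", call. = FALSE)
  sel <- e$pulse_times >= t0 & e$pulse_times < t1
  sum(e$pulse_amplitudes[sel])
}

#' Compare integrated current between stimulus classes
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction) on per-stimulus integrated current in a window -- the
#' stimulus-level control verifying that overall current cannot cue the
#' figure/ground distinction.
#'
#' @param ground List of `electrodogram`s for ground-only stimuli.
#' @param figure List of `electrodogram`s for figure+ground stimuli.
#' @param window Length-2 window in seconds (default `c(2, 4)`, where the
#'   figure can emerge).
#' @return A list of class `current_comparison`: `ground_current`,
#'   `figure_current`, `statistic` (rank-sum W), `p_value`.
#' @export
compare_current_levels <- function(ground, figure, window = c(2, 4)) {
  if (!length(ground) || !length(figure)) {
    stop("both stimulus groups must be non-empty", call. = FALSE)
  }
  gc <- vapply(ground, integrated_current, numeric(1), t0 = window[1],
               t1 = window[2])
  fc <- vapply(figure, integrated_current, numeric(1), t0 = window[1],
               t1 = window[2])
  wt <- stats::wilcox.test(gc, fc, exact = FALSE, correct = TRUE)
  structure(
    list(ground_current = gc, figure_current = fc,
         statistic = unname(wt$statistic), p_value = wt$p.value,
         window = window),
    class = "current_comparison"
  )
}

#' @export
print.current_comparison <- function(x, ...) {
  cat(sprintf(paste0("Integrated current, %g-%g s window: ground median %.2f ",
                     "(n=%d), figure median %.2f (n=%d)\n",
                     "Wilcoxon rank-sum W = %.1f, two-sided p = %.3f\n"),
              x$window[1], x$window[2], stats::median(x$ground_current),
              length(x$ground_current), stats::median(x$figure_current),
              length(x$figure_current), x$statistic, x$p_value))
  invisible(x)
}
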