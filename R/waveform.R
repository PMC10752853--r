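# Shared audio container and utilities: ramps, RMS equalization, level
# roving, and minimal 16-bit PCM RIFF WAV input/output.

#' Construct a waveform object
#'
#' A waveform is sampled audio on a dimensionless full-scale (+/-1) axis with
#' a sample rate and a nominal presentation level carried as metadata. All
#' synthesis functions in the package return this class.
#'
#' @param samples Numeric vector of samples; must be finite.
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param level_db_spl Nominal presentation level in dB SPL, metadata only
#'   (default 70).
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate = 44100, level_db_spl = 70) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("waveform samples must be finite", call. = FALSE)
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be positive", call. = FALSE)
  }
  structure(
    list(samples = samples, sample_rate = sample_rate,
         level_db_spl = level_db_spl),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %.4f s at %g Hz, peak %.3f, rms %.4f, %g dB SPL nominal>\n",
              duration(x), x$sample_rate, max(abs(x$samples)), rms(x),
              x$level_db_spl))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

#' Duration of a waveform in seconds
#' @param x A `waveform`.
#' @return Duration in seconds.
#' @export
duration <- function(x) length(x$samples) / x$sample_rate

#' Root-mean-square amplitude
#' @param x A `waveform` or numeric vector.
#' @return RMS value (dimensionless full-scale units).
#' @export
rms <- function(x) {
  s <- if (inherits(x, "waveform")) x$samples else as.numeric(x)
  sqrt(mean(s^2))
}

#' Apply linear onset/offset ramps
#'
#' @param x A `waveform`.
#' @param ramp_ms Rise/fall time in milliseconds.
#' @return The ramped `waveform`.
#' @export
apply_ramp <- function(x, ramp_ms) {
  n <- round(x$sample_rate * ramp_ms / 1000)
  if (n <= 0) return(x)
  if (2 * n > length(x$samples)) stop("ramps longer than waveform", call. = FALSE)
  env <- rep(1, length(x$samples))
  env[seq_len(n)] <- seq(0, 1, length.out = n)
  env[seq(length(env) - n + 1, length(env))] <- seq(1, 0, length.out = n)
  x$samples <- x$samples * env
  x
}

# raised-cosine on/off flanks used for individual tone pips
raised_cosine_env <- function(n_total, n_ramp) {
  env <- rep(1, n_total)
  if (n_ramp > 0) {
    r <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = n_ramp)))
    env[seq_len(n_ramp)] <- r
    env[seq(n_total - n_ramp + 1, n_total)] <- rev(r)
  }
  env
}

#' Scale a waveform to a target RMS
#' @param x A `waveform`.
#' @param target_rms Desired RMS (default 0.05 full scale).
#' @return Rescaled `waveform`.
#' @export
set_rms <- function(x, target_rms = 0.05) {
  r <- rms(x)
  if (r == 0) stop("cannot RMS-equalize a silent waveform", call. = FALSE)
  x$samples <- x$samples * (target_rms / r)
  x
}

#' Scale a waveform to a target peak amplitude
#' @param x A `waveform`.
#' @param peak Target absolute peak (default 0.5).
#' @return Rescaled `waveform`.
#' @export
set_peak <- function(x, peak = 0.5) {
  m <- max(abs(x$samples))
  if (m == 0) stop("cannot peak-normalize a silent waveform", call. = FALSE)
  x$samples <- x$samples * (peak / m)
  x
}

#' Apply a level offset in dB
#' @param x A `waveform`.
#' @param gain_db Gain in dB (positive amplifies).
#' @return Scaled `waveform`.
#' @export
apply_gain_db <- function(x, gain_db) {
  x$samples <- x$samples * 10^(gain_db / 20)
  x
}

#' Write a waveform to a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer (mono, 16-bit little-endian PCM). Samples are
#' clipped to +/-1 before quantization.
#'
#' @param x A `waveform`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path) {
  stopifnot(inherits(x, "waveform"))
  s <- pmin(pmax(x$samples, -1), 1)
  pcm <- as.integer(round(s * 32767))
  fs <- as.integer(x$sample_rate)
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")        # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file written by [write_wav()]
#'
#' @param path WAV file path.
#' @return A `waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found", call. = FALSE)
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only mono PCM supported", call. = FALSE)
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "raw", n = sz - 8))
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", n = sz / 2, size = 2, signed = TRUE,
                     endian = "little")
      return(waveform(pcm / 32767, sample_rate = sample_rate))
    } else {
      invisible(readBin(con, "raw", n = sz))
    }
  }
}
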