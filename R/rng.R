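# Seed plumbing. Every generator in the package is a pure function of
# (spec, seed): randomness is drawn inside a with_seed() block that saves and
# restores the caller's RNG state, and session-level seeds are split into
# per-trial streams with derive_seed() so individual trials are reproducible
# in isolation.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the random-number generator seeded to `seed`, then
#' restores the caller's RNG state, so package generators never disturb the
#' global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Derive a per-item seed from a session seed
#'
#' Deterministic splitting of one session seed into independent per-trial
#' streams; all arithmetic stays exact in double precision and the result is
#' a valid 31-bit seed.
#'
#' @param seed Session seed (integer).
#' @param i Stream index (non-negative integer).
#' @return An integer seed.
#' @keywords internal
derive_seed <- function(seed, i) {
  s <- (abs(as.numeric(seed)) %% 2147483647)
  as.integer((s * 2654435 + as.numeric(i) * 9973 + 1) %% 2147483647)
}
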