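# Independent oracles used across tests; none of these call the package
# functions they are used to check.

# analytic-signal (Hilbert) envelope via the FFT
analytic_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# envelope smoothed to below cutoff_hz (removes carrier beating, keeps AM)
smoothed_envelope <- function(x, sample_rate, cutoff_hz = 60) {
  env <- analytic_envelope(x)
  n <- length(env)
  E <- stats::fft(env)
  kmax <- floor(cutoff_hz * n / sample_rate)
  keep <- c(seq_len(kmax + 1), seq(n - kmax + 1, n))
  Ef <- complex(n)
  Ef[keep] <- E[keep]
  Re(stats::fft(Ef, inverse = TRUE) / n)
}

# smoothed power spectrum in dB, averaged in log-frequency bins
band_spectrum_db <- function(wf, f_lo = 150, f_hi = 7800, bins_per_octave = 8) {
  s <- stats::spec.pgram(stats::ts(wf$samples, frequency = wf$sample_rate),
                         spans = 31, plot = FALSE, taper = 0)
  keep <- s$freq > f_lo & s$freq < f_hi
  bins <- cut(log2(s$freq[keep] / f_lo),
              breaks = seq(0, log2(f_hi / f_lo), by = 1 / bins_per_octave))
  tapply(10 * log10(s$spec[keep]), bins, mean)
}

# brute-force grid Bayes posterior mean for the three-parameter logistic,
# by direct summation (no log-space tricks)
brute_force_posterior_mean <- function(alpha_grid, beta_grid, gamma_grid,
                                       alpha_prior, logbeta_prior, gamma_prior,
                                       xs, corrects) {
  g <- expand.grid(alpha = alpha_grid, beta = beta_grid, gamma = gamma_grid)
  w <- stats::dnorm(g$alpha, alpha_prior[1], alpha_prior[2]) *
    stats::dnorm(log(g$beta), logbeta_prior[1], logbeta_prior[2]) *
    stats::dbeta(g$gamma, gamma_prior[1], gamma_prior[2])
  for (i in seq_along(xs)) {
    p <- g$gamma + (1 - g$gamma) / (1 + exp(-g$beta * (xs[i] - g$alpha)))
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    w <- w * if (corrects[i]) p else (1 - p)
  }
  w <- w / sum(w)
  c(alpha = sum(w * g$alpha), beta = sum(w * g$beta), gamma = sum(w * g$gamma))
}

# exact rank-sum p-value by full enumeration of group assignments (small n)
permutation_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(x)
  r <- rank(all_v)
  obs <- sum(r[seq_len(n)])
  combs <- utils::combn(length(all_v), n)
  sums <- colSums(matrix(r[combs], nrow = n))
  mean(abs(sums - mean(sums)) >= abs(obs - mean(sums)) - 1e-9)
}

# one simulated yes/no figure-ground session under the equal-variance SDT
# observer, returning the estimated d-prime (oracle path: raw rnorm draws)
simulate_sdt_session <- function(dprime_true, n_trials = 120,
                                 criterion = dprime_true / 2) {
  labels <- sample(rep(c(TRUE, FALSE), each = n_trials / 2))
  evidence <- stats::rnorm(n_trials, mean = dprime_true * labels, sd = 1)
  responses <- evidence > criterion
  score_sfg_session(labels, responses)$dprime
}
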