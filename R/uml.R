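# Updated maximum-likelihood (UML) Bayesian adaptive procedure. The
# psychometric function is a three-parameter logistic (threshold/crossover
# alpha, slope beta, guess rate gamma); the posterior over (alpha, beta,
# gamma) lives on a fixed 3-D grid in log space, is refit after every
# response, and the next stimulus is drawn from the sweet points of the
# current posterior-mean function (low/mid/high cycling; the mid point sits
# near the p = 0.707-equivalent of the 3AFC function).

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Three-parameter logistic psychometric parameters
#'
#' @param alpha Crossover/threshold on the stimulus scale (dB of depth).
#' @param beta Slope, per dB; must be positive.
#' @param gamma Guess rate (lower asymptote), in `[0, 1]`; 1/3 for 3AFC.
#' @return A list of class `psychometric_params`.
#' @export
psychometric_params <- function(alpha, beta, gamma = 1 / 3) {
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "psychometric_params")
}

#' Probability correct under the three-parameter logistic
#'
#' `p(x) = gamma + (1 - gamma) / (1 + exp(-beta * (x - alpha)))`. At
#' `x = alpha` this is the crossover, midway between the guess rate and 1.
#'
#' @param x Stimulus value(s), dB of depth.
#' @param params A [psychometric_params()] (or list with alpha/beta/gamma).
#' @return Probability of a correct response, in `[gamma, 1)`.
#' @export
psychometric_probability <- function(x, params) {
  params$gamma + (1 - params$gamma) * stats::plogis(params$beta * (x - params$alpha))
}

#' Configuration for the UML adaptive procedure
#'
#' Parameter grids, priors, stimulus domain and track length. The defaults
#' suit a 3AFC modulation-depth task on a negative-dB depth scale (0 dB =
#' full modulation): alpha prior Normal(-18, 10) dB, log-slope prior
#' Normal(0, 0.5), Beta(8, 16) prior on the guess rate (mean 1/3). All
#' posterior arithmetic is done in log space on the grid.
#'
#' @param domain Length-2 stimulus range in dB of depth.
#' @param alpha_grid Threshold grid (default 61 points over `domain`).
#' @param beta_grid Slope grid (default 21 log-spaced points, 0.22-4.5 /dB).
#' @param gamma_grid Guess-rate grid (default 11 points, 0.15-0.55).
#' @param alpha_prior `c(mean, sd)` of the Normal prior on alpha (dB).
#' @param logbeta_prior `c(mean, sd)` of the Normal prior on log(beta).
#' @param gamma_prior `c(shape1, shape2)` of the Beta prior on gamma.
#' @param n_trials Number of adaptive trials (default 70).
#' @param sweet_cycle Order in which the low/mid/high sweet points are
#'   visited across trials.
#' @return A list of class `uml_config`.
#' @export
uml_config <- function(domain = c(-40, 0),
                       alpha_grid = seq(domain[1], domain[2], length.out = 61),
                       beta_grid = exp(seq(-1.5, 1.5, length.out = 21)),
                       gamma_grid = seq(0.15, 0.55, length.out = 11),
                       alpha_prior = c(mean(domain) + diff(domain) / 20, 10),
                       logbeta_prior = c(0, 0.5),
                       gamma_prior = c(8, 16),
                       n_trials = 70,
                       sweet_cycle = c("mid", "low", "high")) {
  if (length(domain) != 2 || domain[1] >= domain[2]) {
    stop("domain must be an increasing length-2 range", call. = FALSE)
  }
  if (!length(alpha_grid) || !length(beta_grid) || !length(gamma_grid)) {
    stop("parameter grids must be non-empty", call. = FALSE)
  }
  if (any(beta_grid <= 0)) stop("beta grid must be positive", call. = FALSE)
  if (any(gamma_grid < 0 | gamma_grid >= 1)) {
    stop("gamma grid must lie in [0, 1)", call. = FALSE)
  }
  if (alpha_prior[2] <= 0 || logbeta_prior[2] <= 0 || any(gamma_prior <= 0)) {
    stop("priors must be proper (positive scale parameters)", call. = FALSE)
  }
  if (!all(sweet_cycle %in% c("low", "mid", "high"))) {
    stop("sweet_cycle entries must be 'low', 'mid' or 'high'", call. = FALSE)
  }
  structure(
    list(domain = domain, alpha_grid = alpha_grid, beta_grid = beta_grid,
         gamma_grid = gamma_grid, alpha_prior = alpha_prior,
         logbeta_prior = logbeta_prior, gamma_prior = gamma_prior,
         n_trials = n_trials, sweet_cycle = sweet_cycle),
    class = "uml_config"
  )
}

#' UML configuration preset for the temporal-modulation task
#'
#' Depth scale `20*log10(m)` dB (0 = full modulation); domain -40 to 0 dB.
#' @param ... Overrides passed to [uml_config()].
#' @return A `uml_config`.
#' @export
uml_config_tm <- function(...) uml_config(domain = c(-40, 0), ...)

#' UML configuration preset for the spectral-ripple task
#'
#' Peak-to-trough ripple depth in dB; domain 0 to 40 dB, alpha prior
#' Normal(15, 10).
#' @param ... Overrides passed to [uml_config()].
#' @return A `uml_config`.
#' @export
uml_config_ripple <- function(...) {
  uml_config(domain = c(0, 40),
             alpha_prior = c(15, 10), ...)
}

# sweet points of a three-parameter logistic: stimulus values minimizing the
# expected variance p(1-p)/(dp/dtheta)^2 of the alpha (mid) and beta
# (low/high, one on each side of alpha) estimates; evaluated numerically on
# a dense grid over the stimulus domain and clamped to it.
sweet_points <- function(params, domain, n_eval = 401) {
  x <- seq(domain[1], domain[2], length.out = n_eval)
  L <- stats::plogis(params$beta * (x - params$alpha))
  p <- params$gamma + (1 - params$gamma) * L
  v <- p * (1 - p)
  dalpha <- (1 - params$gamma) * params$beta * L * (1 - L)
  dbeta <- (1 - params$gamma) * abs(x - params$alpha) * L * (1 - L)
  I_alpha <- v / pmax(dalpha^2, 1e-300)
  I_beta <- v / pmax(dbeta^2, 1e-300)
  mid <- x[which.min(I_alpha)]
  below <- x < params$alpha
  above <- x > params$alpha
  low <- if (any(below)) x[below][which.min(I_beta[below])] else domain[1]
  high <- if (any(above)) x[above][which.min(I_beta[above])] else domain[2]
  c(low = max(low, domain[1]), mid = min(max(mid, domain[1]), domain[2]),
    high = min(high, domain[2]))
}

#' Start a UML track
#'
#' Initializes the grid posterior to the prior and selects the first
#' stimulus from the prior's sweet points.
#'
#' @param config A [uml_config()].
#' @return An object of class `uml`: posterior grid, empty history, and
#'   `next_x`, the stimulus to present.
#' @export
uml_start <- function(config = uml_config()) {
  stopifnot(inherits(config, "uml_config"))
  g <- expand.grid(alpha = config$alpha_grid, beta = config$beta_grid,
                   gamma = config$gamma_grid, KEEP.OUT.ATTRS = FALSE)
  logprior <- stats::dnorm(g$alpha, config$alpha_prior[1], config$alpha_prior[2],
                           log = TRUE) +
    stats::dnorm(log(g$beta), config$logbeta_prior[1], config$logbeta_prior[2],
                 log = TRUE) +
    stats::dbeta(g$gamma, config$gamma_prior[1], config$gamma_prior[2],
                 log = TRUE)
  if (!all(is.finite(logprior))) {
    stop("improper prior: non-finite density on the grid", call. = FALSE)
  }
  logpost <- logprior - logsumexp(logprior)
  state <- structure(
    list(config = config, grid = g, logpost = logpost,
         history = data.frame(trial = integer(0), x = numeric(0),
                              correct = logical(0), alpha_est = numeric(0),
                              beta_est = numeric(0), gamma_est = numeric(0)),
         next_x = NA_real_),
    class = "uml"
  )
  state$next_x <- uml_select_stimulus(state)
  state
}

#' Posterior-mean psychometric parameters
#'
#' @param state A `uml` state.
#' @return A [psychometric_params()] of posterior means.
#' @export
uml_estimate <- function(state) {
  stopifnot(inherits(state, "uml"))
  w <- exp(state$logpost - max(state$logpost))
  w <- w / sum(w)
  psychometric_params(alpha = sum(w * state$grid$alpha),
                      beta = sum(w * state$grid$beta),
                      gamma = sum(w * state$grid$gamma))
}

#' Select the next stimulus for a UML track
#'
#' Applies the sweet-point rule to the current posterior-mean function,
#' cycling through the configured low/mid/high order by trial number; the
#' returned value is always inside the stimulus domain.
#'
#' @param state A `uml` state.
#' @return A stimulus value in dB of depth.
#' @export
uml_select_stimulus <- function(state) {
  stopifnot(inherits(state, "uml"))
  if (nrow(state$history) >= state$config$n_trials) {
    stop("UML session complete: no further stimuli", call. = FALSE)
  }
  est <- uml_estimate(state)
  sp <- sweet_points(est, state$config$domain)
  cyc <- state$config$sweet_cycle
  unname(sp[cyc[(nrow(state$history) %% length(cyc)) + 1]])
}

#' Update a UML track with one response
#'
#' Adds the Bernoulli log-likelihood of the response at stimulus `x`
#' pointwise to the log-posterior, renormalizes, appends the trial to the
#' history with running estimates, and selects the next stimulus.
#'
#' @param state A `uml` state.
#' @param x Stimulus presented (dB of depth), inside the domain.
#' @param correct Logical response.
#' @return The updated `uml` state.
#' @export
uml_update <- function(state, x, correct) {
  stopifnot(inherits(state, "uml"), is.logical(correct), length(correct) == 1)
  if (nrow(state$history) >= state$config$n_trials) {
    stop("UML session complete: cannot update further", call. = FALSE)
  }
  if (x < state$config$domain[1] - 1e-9 || x > state$config$domain[2] + 1e-9) {
    stop("stimulus outside the configured domain", call. = FALSE)
  }
  p <- state$grid$gamma +
    (1 - state$grid$gamma) * stats::plogis(state$grid$beta * (x - state$grid$alpha))
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  ll <- if (correct) log(p) else log(1 - p)
  logpost <- state$logpost + ll
  state$logpost <- logpost - logsumexp(logpost)
  est <- uml_estimate(state)
  state$history <- rbind(
    state$history,
    data.frame(trial = nrow(state$history) + 1L, x = x, correct = correct,
               alpha_est = est$alpha, beta_est = est$beta, gamma_est = est$gamma)
  )
  state$next_x <- if (nrow(state$history) < state$config$n_trials) {
    uml_select_stimulus(state)
  } else {
    NA_real_
  }
  state
}

#' @export
print.uml <- function(x, ...) {
  est <- uml_estimate(x)
  cat(sprintf(paste0("<uml: %d/%d trials; posterior mean alpha = %.2f dB, ",
                     "beta = %.2f /dB, gamma = %.3f>\n"),
              nrow(x$history), x$config$n_trials, est$alpha, est$beta, est$gamma))
  invisible(x)
}

#' @export
coef.uml <- function(object, ...) {
  est <- uml_estimate(object)
  c(alpha = est$alpha, beta = est$beta, gamma = est$gamma)
}

#' Run a full adaptive session against a simulated observer
#'
#' Presents `config$n_trials` stimuli chosen by the UML rule; responses are
#' Bernoulli draws from the observer's psychometric function. Optional
#' practice trials (easy stimuli at the top of the domain) are presented
#' first and excluded from inference.
#'
#' @param config A [uml_config()].
#' @param observer A [psychometric_params()] describing the simulated
#'   listener.
#' @param seed Integer seed; fixes the whole response sequence.
#' @param n_practice Number of practice trials to simulate and discard.
#' @return A list with elements `state` (final `uml`) and `estimate`
#'   ([psychometric_params()] of posterior means).
#' @export
run_adaptive_session <- function(config = uml_config(), observer, seed,
                                 n_practice = 0) {
  stopifnot(inherits(observer, "psychometric_params"))
  state <- uml_start(config)
  with_seed(seed, {
    for (i in seq_len(n_practice)) {
      p <- psychometric_probability(config$domain[2], observer)
      invisible(stats::runif(1) < p)  # feedback trial, not used for inference
    }
    for (i in seq_len(config$n_trials)) {
      x <- state$next_x
      correct <- stats::runif(1) < psychometric_probability(x, observer)
      state <- uml_update(state, x, correct)
    }
  })
  list(state = state, estimate = uml_estimate(state))
}
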