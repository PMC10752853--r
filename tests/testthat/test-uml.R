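test_that("three-parameter logistic has the right crossover and asymptotes", {
  p <- psychometric_params(alpha = -10, beta = 1, gamma = 1 / 3)
  expect_equal(psychometric_probability(-10, p), 1 / 3 + (1 - 1 / 3) / 2)
  expect_equal(psychometric_probability(-10, p), 2 / 3)
  expect_equal(psychometric_probability(1e6, p), 1, tolerance = 1e-12)
  expect_equal(psychometric_probability(-1e6, p), 1 / 3, tolerance = 1e-12)
  g <- psychometric_params(0, 2, 0.25)
  expect_equal(psychometric_probability(0, g), 0.25 + 0.75 / 2)
  expect_error(psychometric_params(0, -1), "beta")
  expect_error(psychometric_params(0, 1, 1.5), "gamma")
})

test_that("prior-only state reproduces the prior and normalizes", {
  # alpha grid symmetric about the prior mean so truncation is exact
  cfg <- uml_config(domain = c(-38, 2),
                    alpha_grid = seq(-28, -8, length.out = 41),
                    alpha_prior = c(-18, 5))
  st <- uml_start(cfg)
  expect_equal(sum(exp(st$logpost)), 1, tolerance = 1e-10)
  est <- uml_estimate(st)
  expect_equal(est$alpha, -18, tolerance = 1e-9)
  st2 <- uml_start(cfg)
  expect_identical(st$next_x, st2$next_x)
})

test_that("updates match a brute-force grid Bayes oracle", {
  ag <- seq(-30, -6, length.out = 5)
  bg <- exp(seq(-1, 1, length.out = 5))
  gg <- seq(0.2, 0.45, length.out = 5)
  cfg <- uml_config(domain = c(-40, 0), alpha_grid = ag, beta_grid = bg,
                    gamma_grid = gg)
  st <- uml_start(cfg)
  xs <- c(-20, -12, -25, -18, -9, -30)
  ok <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  for (i in seq_along(xs)) st <- uml_update(st, xs[i], ok[i])
  oracle <- brute_force_posterior_mean(ag, bg, gg, cfg$alpha_prior,
                                       cfg$logbeta_prior, cfg$gamma_prior,
                                       xs, ok)
  est <- uml_estimate(st)
  expect_equal(est$alpha, unname(oracle["alpha"]), tolerance = 1e-8)
  expect_equal(est$beta, unname(oracle["beta"]), tolerance = 1e-8)
  expect_equal(est$gamma, unname(oracle["gamma"]), tolerance = 1e-8)
  expect_equal(sum(exp(st$logpost)), 1, tolerance = 1e-10)
  expect_true(all(is.finite(st$logpost)))
})

test_that("many correct responses at low levels pull alpha below the prior", {
  cfg <- uml_config()
  st <- uml_start(cfg)
  prior_alpha <- uml_estimate(st)$alpha
  for (i in 1:15) st <- uml_update(st, -35, TRUE)
  expect_lt(uml_estimate(st)$alpha, prior_alpha)
})

test_that("alternating outcomes at a fixed level pin the fitted function to p = 0.5 there", {
  # an empirical rate of 1/2 at one level cannot pin alpha and beta jointly
  # for a 3AFC function (p = 0.5 sits log(3)/beta below the crossover); the
  # convergent property is that the fitted function passes through (x0, 0.5),
  # with alpha landing above x0 by that offset
  cfg <- uml_config(n_trials = 200)
  st <- uml_start(cfg)
  x0 <- -24
  for (i in 1:200) st <- uml_update(st, x0, i %% 2 == 0)
  w <- exp(st$logpost)
  p_grid <- st$grid$gamma + (1 - st$grid$gamma) *
    plogis(st$grid$beta * (x0 - st$grid$alpha))
  predictive <- sum(w * p_grid)
  expect_lt(abs(predictive - 0.5), 0.03)
  # alpha sits above the p = 0.5 level for a 3AFC function
  expect_gt(uml_estimate(st)$alpha, x0)
})

test_that("stimulus selection honors point-mass posteriors and the domain", {
  cfg <- uml_config()
  st <- uml_start(cfg)
  # force a point mass at a grid vertex
  target <- which(abs(st$grid$alpha + 20) < 1e-9 &
                    abs(st$grid$beta - 1) < 0.05 &
                    abs(st$grid$gamma - 1 / 3) < 0.02)[1]
  st$logpost <- rep(-1e6, nrow(st$grid))
  st$logpost[target] <- 0
  est <- uml_estimate(st)
  sp_x <- uml_select_stimulus(st)
  expect_gte(sp_x, cfg$domain[1])
  expect_lte(sp_x, cfg$domain[2])
  # mid sweet point of the point-mass function sits above alpha (p ~ 0.7)
  p_at_sel <- psychometric_probability(sp_x, est)
  expect_gt(p_at_sel, 0.5)
  expect_lt(p_at_sel, 0.95)
})

test_that("sequential updates equal one batch posterior exactly", {
  cfg <- uml_config(alpha_grid = seq(-35, -5, length.out = 13),
                    beta_grid = exp(seq(-1, 1, length.out = 7)),
                    gamma_grid = seq(0.2, 0.45, length.out = 5))
  xs <- c(-10, -22, -17, -28)
  ok <- c(TRUE, FALSE, TRUE, TRUE)
  st_seq <- uml_start(cfg)
  for (i in seq_along(xs)) st_seq <- uml_update(st_seq, xs[i], ok[i])
  st_batch <- uml_start(cfg)
  lp <- st_batch$logpost
  for (i in seq_along(xs)) {
    p <- st_batch$grid$gamma + (1 - st_batch$grid$gamma) *
      stats::plogis(st_batch$grid$beta * (xs[i] - st_batch$grid$alpha))
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    lp <- lp + if (ok[i]) log(p) else log(1 - p)
  }
  lp <- lp - max(lp) - log(sum(exp(lp - max(lp))))
  expect_equal(st_seq$logpost, lp, tolerance = 1e-10)
})

test_that("sessions run to length, are deterministic, then refuse updates", {
  obs <- psychometric_params(-15, 1, 1 / 3)
  cfg <- uml_config(n_trials = 25)
  r1 <- run_adaptive_session(cfg, obs, seed = 11)
  r2 <- run_adaptive_session(cfg, obs, seed = 11)
  expect_equal(nrow(r1$state$history), 25)
  expect_identical(r1$state$history, r2$state$history)
  expect_error(uml_update(r1$state, -15, TRUE), "complete")
  expect_error(uml_select_stimulus(r1$state), "complete")
  r3 <- run_adaptive_session(cfg, obs, seed = 12)
  expect_false(identical(r1$state$history$correct, r3$state$history$correct))
})

test_that("selected stimuli concentrate near the observer threshold", {
  hits <- 0L
  total <- 0L
  for (seed in 1:20) {
    obs <- psychometric_params(-18, 1, 1 / 3)
    r <- run_adaptive_session(uml_config(), obs, seed = 300 + seed)
    late <- r$state$history$x[21:70]
    hits <- hits + sum(abs(late - obs$alpha) <= 10)
    total <- total + length(late)
  }
  expect_gte(hits / total, 0.8)
})

test_that("information accumulates: threshold RMSE shrinks from trial 20 to 70", {
  err20 <- err70 <- numeric(60)
  for (i in seq_len(60)) {
    a_true <- -30 + 22 * (i - 1) / 59
    obs <- psychometric_params(a_true, 1, 1 / 3)
    r <- run_adaptive_session(uml_config(), obs, seed = 5000 + i)
    err20[i] <- r$state$history$alpha_est[20] - a_true
    err70[i] <- r$state$history$alpha_est[70] - a_true
  }
  expect_lt(sqrt(mean(err70^2)), sqrt(mean(err20^2)))
})

test_that("estimates are equivariant under a shift of the stimulus axis", {
  shift <- 7
  cfg1 <- uml_config()
  cfg2 <- uml_config(domain = cfg1$domain + shift,
                     alpha_grid = cfg1$alpha_grid + shift,
                     alpha_prior = c(cfg1$alpha_prior[1] + shift,
                                     cfg1$alpha_prior[2]))
  xs <- c(-20, -15, -25, -10, -18)
  ok <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  s1 <- uml_start(cfg1)
  s2 <- uml_start(cfg2)
  for (i in seq_along(xs)) {
    s1 <- uml_update(s1, xs[i], ok[i])
    s2 <- uml_update(s2, xs[i] + shift, ok[i])
  }
  expect_equal(uml_estimate(s2)$alpha, uml_estimate(s1)$alpha + shift,
               tolerance = 1e-8)
  expect_equal(uml_estimate(s2)$beta, uml_estimate(s1)$beta, tolerance = 1e-8)
})

test_that("an always-correct observer keeps the track stable and is read as easy-everywhere", {
  obs <- psychometric_params(-15, 1, gamma = 1)  # responds correctly always
  cfg <- uml_config(n_trials = 30)
  r <- run_adaptive_session(cfg, obs, seed = 2)
  st <- uml_start(cfg)
  prior <- uml_estimate(st)
  # posterior stays proper and finite throughout
  expect_equal(sum(exp(r$state$logpost)), 1, tolerance = 1e-10)
  expect_true(all(is.finite(r$state$logpost)))
  # a uniformly correct history is evidence that every tested level is above
  # threshold: alpha is pulled below the prior, the guess rate upward
  expect_lt(r$estimate$alpha, prior$alpha)
  expect_gte(r$estimate$gamma, prior$gamma - 0.02)
})

test_that("improper configurations are rejected", {
  expect_error(uml_config(alpha_prior = c(-18, -1)), "proper")
  expect_error(uml_config(domain = c(0, -10)), "range")
  expect_error(uml_config(gamma_grid = c(0.5, 1)), "gamma")
})
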