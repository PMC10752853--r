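make_cohort_like <- function(n, seed) {
  set.seed(seed)
  data.frame(
    sfg_dprime = rnorm(n, 1.5, 0.6),
    ripple_crossover_db = rnorm(n, 12, 4),
    tm_crossover_db = rnorm(n, -15, 5),
    azbio_proportion = runif(n, 0.2, 0.9),
    acoustic_threshold_db_hl = rnorm(n, 59, 20)
  )
}

test_that("orthogonal predictors give beta equal to bivariate r", {
  set.seed(1)
  # center first, then orthogonalize: columns stay zero-mean, so they remain
  # exactly orthogonal after standardization
  M <- scale(matrix(rnorm(60 * 3), 60, 3), center = TRUE, scale = FALSE)
  X <- scale(qr.Q(qr(M)))
  y <- rnorm(60)
  d <- data.frame(azbio_proportion = y, sfg_dprime = X[, 1],
                  ripple_crossover_db = X[, 2], tm_crossover_db = X[, 3])
  fit <- fit_speech_model(d)
  # columns are orthogonal after centering too (qr.Q then scale)
  for (i in seq_len(3)) {
    expect_equal(unname(coef(fit)[i]), cor(X[, i], y), tolerance = 1e-10)
  }
})

test_that("a noise-free linear outcome gives R-squared one", {
  d <- make_cohort_like(30, 3)
  d$azbio_proportion <- 0.5 + 0.1 * d$sfg_dprime - 0.01 * d$ripple_crossover_db +
    0.005 * d$tm_crossover_db
  # lm warns about the essentially perfect fit; that is the point here
  fit <- suppressWarnings(fit_speech_model(d))
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-10)
})

test_that("squared t equals the drop-one nested-model F", {
  d <- make_cohort_like(47, 7)
  d$azbio_proportion <- 0.5 + 0.05 * d$sfg_dprime -
    0.01 * d$ripple_crossover_db - 0.01 * d$tm_crossover_db +
    rnorm(47, 0, 0.1)
  fit <- fit_speech_model(d)
  full <- lm(azbio_proportion ~ sfg_dprime + ripple_crossover_db +
               tm_crossover_db, data = d)
  for (v in fit$predictors) {
    reduced <- lm(stats::reformulate(setdiff(fit$predictors, v),
                                     response = "azbio_proportion"), data = d)
    f_drop <- anova(reduced, full)$F[2]
    expect_equal(fit$coefficients[v, "t"]^2, f_drop, tolerance = 1e-8)
  }
})

test_that("partial-residual correlations reproduce the model's partial rho", {
  d <- make_cohort_like(47, 11)
  fit <- fit_speech_model(d)
  for (v in fit$predictors) {
    pr <- partial_residual(fit, v, residualize_x = TRUE)
    expect_equal(cor(pr$x, pr$outcome_residual),
                 fit$coefficients[v, "partial_rho"], tolerance = 1e-10)
    # sign of partial rho always matches the coefficient sign
    expect_equal(sign(fit$coefficients[v, "partial_rho"]),
                 sign(fit$coefficients[v, "beta_normalized"]))
  }
  expect_error(partial_residual(fit, "nonexistent"), "unknown predictor")
})

test_that("single-predictor partial residual is the centered outcome", {
  d <- make_cohort_like(30, 5)
  fit <- fit_speech_model(d, predictors = "sfg_dprime")
  pr <- partial_residual(fit, "sfg_dprime")
  expect_equal(pr$outcome_residual,
               unname(d$azbio_proportion - mean(d$azbio_proportion)),
               tolerance = 1e-12)
})

test_that("normalized beta is invariant to affine rescaling of inputs", {
  d <- make_cohort_like(47, 13)
  fit1 <- fit_speech_model(d)
  d2 <- d
  d2$ripple_crossover_db <- 3 * d2$ripple_crossover_db - 100
  d2$azbio_proportion <- 0.5 * d2$azbio_proportion + 0.2
  fit2 <- fit_speech_model(d2)
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-10)
  expect_equal(fit1$r_squared, fit2$r_squared, tolerance = 1e-10)
})

test_that("model arithmetic matches the reported-statistic identities", {
  expect_lte(adjusted_r_squared(0.463, 47, 3), 0.463)
  expect_equal(round(adjusted_r_squared(0.463, 47, 3), 3), 0.426)
  expect_equal(round(f_from_r_squared(0.463, 47, 3), 1), 12.4)
  d <- make_cohort_like(47, 17)
  fit <- fit_speech_model(d)
  expect_equal(fit$adj_r_squared, adjusted_r_squared(fit$r_squared, 47, 3),
               tolerance = 1e-12)
  expect_lte(fit$adj_r_squared, fit$r_squared)
  # F and p agree with the raw lm summary
  sm <- summary(lm(azbio_proportion ~ sfg_dprime + ripple_crossover_db +
                     tm_crossover_db, data = d))
  expect_equal(fit$f_statistic, unname(sm$fstatistic[1]), tolerance = 1e-10)
  expect_equal(fit$r_squared, sm$r.squared, tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  d <- make_cohort_like(47, 19)
  d$tm_crossover_db <- 2 * d$sfg_dprime + 1
  expect_error(fit_speech_model(d), "singular")
  d2 <- make_cohort_like(47, 19)
  d2$ripple_crossover_db <- 5
  expect_error(fit_speech_model(d2), "zero variance")
  expect_error(fit_speech_model(make_cohort_like(4, 1)), "more subjects")
})

test_that("collinearity screen flags duplicates and keeps type-I error near 5%", {
  d <- make_cohort_like(47, 23)
  sc <- collinearity_screen(d)
  expect_equal(unname(diag(sc$r)), rep(1, 4))
  d$dup <- d$sfg_dprime
  sc2 <- collinearity_screen(d, vars = c("sfg_dprime", "dup"))
  expect_equal(sc2$r["sfg_dprime", "dup"], 1)
  expect_lt(sc2$p["sfg_dprime", "dup"], 1e-10)
  expect_equal(nrow(sc2$flagged), 1)
  # type-I rate on independent predictors
  set.seed(101)
  flags <- 0
  n_pairs <- 0
  for (i in 1:300) {
    di <- make_cohort_like(47, 1000 + i)
    sci <- collinearity_screen(di, vars = c("sfg_dprime",
                                            "ripple_crossover_db",
                                            "tm_crossover_db"))
    flags <- flags + nrow(sci$flagged)
    n_pairs <- n_pairs + 3
  }
  expect_lt(abs(flags / n_pairs - 0.05), 0.02)
})

test_that("bivariate correlations behave under identity and null structure", {
  d <- make_cohort_like(47, 29)
  d$azbio_proportion <- d$sfg_dprime
  biv <- bivariate_outcome_correlations(d, vars = "sfg_dprime")
  expect_equal(biv$r, 1, tolerance = 1e-12)
  # null: |r| below the n=47 significance radius in >= 95% of draws
  rs <- vapply(1:300, function(i) {
    di <- make_cohort_like(47, 2000 + i)
    bivariate_outcome_correlations(di, vars = "sfg_dprime")$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
  expect_gte(mean(abs(rs) < 0.29), 0.95)
})

test_that("model methods are coherent", {
  d <- make_cohort_like(47, 31)
  fit <- fit_speech_model(d)
  expect_named(coef(fit), fit$predictors)
  expect_length(predict(fit), 47)
  expect_equal(unname(predict(fit) + residuals(fit)),
               d$azbio_proportion, tolerance = 1e-10)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(47, 2))
  expect_output(print(fit), "R\\^2")
  expect_s3_class(summary(fit), "summary.speech_model")
})
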