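# Simulated observers and cohort generator. Observers obey the same models
# the analysis assumes: a three-parameter logistic for the oddball tasks and
# an equal-variance signal-detection observer for the yes/no figure-ground
# task. The cohort generator draws mutually independent standardized
# predictors and builds the speech outcome from the study's normalized
# effect sizes, giving an end-to-end testbed with no external data.

#' Simulate one oddball response
#'
#' Bernoulli draw from the three-parameter logistic at stimulus `x`.
#'
#' @param params A [psychometric_params()] for the simulated listener.
#' @param x Stimulus value (dB of depth).
#' @param seed Integer seed.
#' @return Logical: correct response?
#' @export
simulate_oddball_observer <- function(params, x, seed) {
  stopifnot(inherits(params, "psychometric_params"))
  with_seed(seed, stats::runif(1) < psychometric_probability(x, params))
}

#' Simulate one yes/no figure-ground response
#'
#' Equal-variance signal-detection observer: internal evidence is
#' Normal(d'_true, 1) on figure trials and Normal(0, 1) on ground trials;
#' the response is "yes" when evidence exceeds the criterion. The unbiased
#' criterion is `d'_true / 2`.
#'
#' @param dprime_true True sensitivity, `>= 0`.
#' @param criterion Decision criterion on the evidence axis.
#' @param is_figure Logical trial label.
#' @param seed Integer seed.
#' @return Logical: "yes" response?
#' @export
simulate_sfg_observer <- function(dprime_true, criterion = dprime_true / 2,
                                  is_figure, seed) {
  if (dprime_true < 0) stop("dprime_true must be >= 0", call. = FALSE)
  with_seed(seed, stats::rnorm(1, mean = dprime_true * is_figure, sd = 1) >
              criterion)
}

#' Generate a synthetic study cohort
#'
#' Standardized predictors (figure-ground d-prime, ripple crossover,
#' temporal-modulation crossover) are drawn independently; the standardized
#' speech outcome is their weighted sum, with weights equal to the
#' normalized effect sizes, plus Gaussian residual noise. With `r2 = NULL`
#' the residual variance is `1 - sum(betas^2)`, so the population normalized
#' coefficients equal `betas` exactly (population R-squared is then
#' `sum(betas^2)`). Supplying a numeric `r2` instead scales the residual so
#' the population R-squared matches it; with independent predictors that
#' necessarily rescales the normalized coefficients by
#' `sqrt(r2 / sum(betas^2))`, since R-squared equals the sum of squared
#' normalized coefficients in that case -- both conventions are offered
#' because a reported (beta, R-squared) pair can only coexist exactly when
#' predictors are correlated. Columns are then mapped to natural units
#' (d-prime, dB, word proportion) by affine transforms, which leave
#' normalized coefficients unchanged; d-prime is floored at 0 and the speech
#' proportion clipped to [0, 1] (both rare by construction, < 1%).
#'
#' @param n_subjects Number of subjects (default 47).
#' @param betas Generating normalized effects for (SFG, ripple, TM);
#'   defaults `c(0.292, -0.250, -0.434)`.
#' @param r2 Target population R-squared (default 0.463), or `NULL` for the
#'   coefficient-faithful mode described above.
#' @param seed Integer seed.
#' @param predictor_cor Optional common pairwise correlation among the
#'   standardized predictors (robustness checks only; default 0).
#' @param natural_units Named list of `c(mean, sd)` for `sfg_dprime`,
#'   `ripple_crossover_db`, `tm_crossover_db`, `azbio_proportion`, plus
#'   `acoustic_threshold_db_hl` (screen-only column, independent of the
#'   model variables).
#' @return A data frame of class `cohort_table` with the five per-subject
#'   columns; generating parameters are attached as attributes.
#' @export
generate_cohort <- function(n_subjects = 47,
                            betas = c(0.292, -0.250, -0.434),
                            r2 = 0.463, seed,
                            predictor_cor = 0,
                            natural_units = list(
                              sfg_dprime = c(1.5, 0.6),
                              ripple_crossover_db = c(12, 4),
                              tm_crossover_db = c(-15, 5),
                              azbio_proportion = c(0.55, 0.18),
                              acoustic_threshold_db_hl = c(59.4, 20.5)
                            )) {
  if (length(betas) != 3) stop("betas must have length 3", call. = FALSE)
  sig2 <- sum(betas^2)
  if (sig2 >= 1) stop("sum(betas^2) must be < 1", call. = FALSE)
  if (!is.null(r2) && (r2 <= 0 || r2 >= 1)) {
    stop("requested r2 must be in (0, 1)", call. = FALSE)
  }
  resid_var <- if (is.null(r2)) 1 - sig2 else sig2 * (1 - r2) / r2
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_subjects * 3), n_subjects, 3)
    if (predictor_cor != 0) {
      R <- matrix(predictor_cor, 3, 3)
      diag(R) <- 1
      Z <- Z %*% chol(R)
    }
    y <- as.numeric(Z %*% betas) + stats::rnorm(n_subjects, 0, sqrt(resid_var))
    y <- y / sqrt(sig2 + resid_var)  # standardize to unit population variance
    nu <- natural_units
    out <- data.frame(
      sfg_dprime = pmax(nu$sfg_dprime[1] + nu$sfg_dprime[2] * Z[, 1], 0),
      ripple_crossover_db = nu$ripple_crossover_db[1] +
        nu$ripple_crossover_db[2] * Z[, 2],
      tm_crossover_db = nu$tm_crossover_db[1] + nu$tm_crossover_db[2] * Z[, 3],
      azbio_proportion = pmin(pmax(nu$azbio_proportion[1] +
                                     nu$azbio_proportion[2] * y, 0), 1),
      acoustic_threshold_db_hl = nu$acoustic_threshold_db_hl[1] +
        nu$acoustic_threshold_db_hl[2] * stats::rnorm(n_subjects)
    )
    attr(out, "betas") <- betas
    attr(out, "r2") <- if (is.null(r2)) sig2 else r2
    attr(out, "seed") <- seed
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Write a cohort table and its generating manifest
#'
#' @param cohort A `cohort_table`.
#' @param path CSV output path; a JSON manifest with the generating
#'   parameters is written alongside it.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  manifest <- list(n_subjects = nrow(cohort),
                   betas = attr(cohort, "betas"),
                   r2 = attr(cohort, "r2"),
                   seed = attr(cohort, "seed"))
  jsonlite::write_json(manifest, sub("\\.csv$", "_manifest.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Measure one subject end to end
#'
#' Runs the full measurement chain for a single simulated subject: two UML
#' adaptive tracks (spectral ripple and temporal modulation) against
#' logistic observers, and a figure-ground yes/no session against a
#' signal-detection observer, scored as d-prime. By default the
#' figure-ground leg simulates trial labels and responses without
#' synthesizing audio (the simulated observer never receives the waveform);
#' set `synthesize_audio = TRUE` to generate the stimuli as well.
#'
#' @param ripple_observer [psychometric_params()] on the ripple-depth scale.
#' @param tm_observer [psychometric_params()] on the modulation-depth scale.
#' @param sfg_dprime_true True figure-ground sensitivity.
#' @param sfg_criterion SDT criterion (default unbiased, `d'/2`).
#' @param n_sfg_trials Figure-ground trials (default 120).
#' @param seed Subject seed.
#' @param ripple_config,tm_config UML configurations for the two tracks.
#' @param synthesize_audio Logical; also generate the figure-ground session
#'   waveforms.
#' @return One-row data frame with `sfg_dprime`, `ripple_crossover_db`,
#'   `tm_crossover_db`.
#' @export
end_to_end_subject <- function(ripple_observer, tm_observer, sfg_dprime_true,
                               sfg_criterion = sfg_dprime_true / 2,
                               n_sfg_trials = 120, seed,
                               ripple_config = uml_config_ripple(),
                               tm_config = uml_config_tm(),
                               synthesize_audio = FALSE) {
  ripple <- run_adaptive_session(ripple_config, ripple_observer,
                                 seed = derive_seed(seed, 1))
  tm <- run_adaptive_session(tm_config, tm_observer,
                             seed = derive_seed(seed, 2))
  if (synthesize_audio) {
    session <- generate_sfg_session(n_trials = n_sfg_trials,
                                    seed = derive_seed(seed, 3))
    labels <- session$is_figure
  } else {
    labels <- with_seed(derive_seed(seed, 3),
                        sample(rep(c(TRUE, FALSE), each = n_sfg_trials / 2)))
  }
  responses <- vapply(seq_along(labels), function(i) {
    simulate_sfg_observer(sfg_dprime_true, sfg_criterion, labels[i],
                          seed = derive_seed(seed, 100 + i))
  }, logical(1))
  scored <- score_sfg_session(labels, responses)
  data.frame(sfg_dprime = scored$dprime,
             ripple_crossover_db = ripple$estimate$alpha,
             tm_crossover_db = tm$estimate$alpha)
}
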