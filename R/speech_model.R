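# Cohort-level inference: predictor collinearity screen, bivariate
# correlations with the speech-in-noise outcome, and the multiple linear
# regression of speech accuracy on figure-ground sensitivity, spectral and
# temporal resolution, reported as normalized (standardized) coefficients
# with partial correlations, R-squared, adjusted R-squared and the overall
# F test.

default_predictors <- c("sfg_dprime", "ripple_crossover_db", "tm_crossover_db")

check_cohort_columns <- function(data, vars) {
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (v in vars) {
    col <- data[[v]]
    if (!is.numeric(col) || anyNA(col)) {
      stop("column '", v, "' must be numeric with no missing values",
           call. = FALSE)
    }
    if (stats::sd(col) == 0) {
      stop("column '", v, "' has zero variance", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Predictor collinearity screen
#'
#' Pairwise Pearson correlations (with two-sided p-values) among candidate
#' predictors, flagging pairs significant at `alpha`. Run before the
#' multiple regression to verify the predictors behave as separate
#' dimensions.
#'
#' @param data Data frame of per-subject measures.
#' @param vars Columns to screen (default: the three model predictors plus
#'   `acoustic_threshold_db_hl` when present).
#' @param alpha Flagging level (default 0.05).
#' @return A list of class `collinearity_screen`: matrices `r` and `p`, and
#'   a data frame `flagged` of significant pairs.
#' @export
collinearity_screen <- function(data, vars = NULL, alpha = 0.05) {
  if (is.null(vars)) {
    vars <- intersect(c(default_predictors, "acoustic_threshold_db_hl"),
                      names(data))
  }
  check_cohort_columns(data, vars)
  if (nrow(data) < 5) stop("need at least 5 subjects", call. = FALSE)
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  diag(p) <- 0
  flagged <- data.frame(var1 = character(0), var2 = character(0),
                        r = numeric(0), p = numeric(0))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      ct <- stats::cor.test(data[[vars[i]]], data[[vars[j]]])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
      if (ct$p.value < alpha) {
        flagged <- rbind(flagged,
                         data.frame(var1 = vars[i], var2 = vars[j],
                                    r = unname(ct$estimate), p = ct$p.value))
      }
    }
  }
  structure(list(r = r, p = p, flagged = flagged, alpha = alpha),
            class = "collinearity_screen")
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat("Predictor collinearity screen (Pearson r):\n")
  print(round(x$r, 3))
  if (nrow(x$flagged)) {
    cat(sprintf("Pairs significant at p < %g:\n", x$alpha))
    print(x$flagged, row.names = FALSE)
  } else {
    cat(sprintf("No pairs significant at p < %g.\n", x$alpha))
  }
  invisible(x)
}

#' Bivariate correlations of each predictor with the outcome
#'
#' @param data Data frame of per-subject measures.
#' @param outcome Outcome column (default `azbio_proportion`).
#' @param vars Predictor columns (default: model predictors plus acoustic
#'   threshold when present).
#' @return Data frame with columns `predictor`, `r`, `p`.
#' @export
bivariate_outcome_correlations <- function(data, outcome = "azbio_proportion",
                                           vars = NULL) {
  if (is.null(vars)) {
    vars <- intersect(c(default_predictors, "acoustic_threshold_db_hl"),
                      names(data))
  }
  check_cohort_columns(data, c(vars, outcome))
  if (nrow(data) < 5) stop("need at least 5 subjects", call. = FALSE)
  res <- lapply(vars, function(v) {
    ct <- stats::cor.test(data[[v]], data[[outcome]])
    data.frame(predictor = v, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, res)
}

#' Fit the speech-in-noise multiple regression
#'
#' Ordinary least squares of the outcome on the three per-subject measures,
#' `azbio ~ 1 + sfg_dprime + ripple_crossover_db + tm_crossover_db`.
#' Normalized coefficients (with their SE, t and p) come from refitting on
#' z-scored outcome and predictors; each predictor's partial correlation is
#' the correlation of the two residual vectors after residualizing predictor
#' and outcome on the remaining predictors. Model-level statistics are
#' R-squared, adjusted R-squared `1 - (1 - R2)(n - 1)/(n - k - 1)`, and the
#' overall F on `(k, n - k - 1)` degrees of freedom.
#'
#' @param data Data frame with the outcome and predictor columns; no missing
#'   values; `n > k + 1` rows.
#' @param outcome Outcome column name (default `azbio_proportion`).
#' @param predictors Predictor column names (default: SFG d-prime, ripple
#'   crossover, temporal-modulation crossover).
#' @return An object of class `speech_model`; see [summary.speech_model()].
#' @export
fit_speech_model <- function(data, outcome = "azbio_proportion",
                             predictors = default_predictors) {
  check_cohort_columns(data, c(outcome, predictors))
  n <- nrow(data)
  k <- length(predictors)
  if (n <= k + 1) stop("need more subjects than predictors + 1", call. = FALSE)
  X <- as.matrix(data[predictors])
  if (qr(cbind(1, X))$rank < k + 1) {
    stop("singular design: predictors are linearly dependent", call. = FALSE)
  }
  form <- stats::reformulate(predictors, response = outcome)
  fit_raw <- stats::lm(form, data = data)
  zdata <- as.data.frame(scale(data[c(outcome, predictors)]))
  fit_z <- stats::lm(form, data = zdata)
  sm <- summary(fit_z)
  coefs <- stats::coef(sm)[predictors, , drop = FALSE]
  # partial correlation: residualize predictor and outcome on the others
  partial_rho <- vapply(predictors, function(v) {
    others <- setdiff(predictors, v)
    if (length(others)) {
      rx <- stats::resid(stats::lm(stats::reformulate(others, response = v),
                                   data = data))
      ry <- stats::resid(stats::lm(stats::reformulate(others, response = outcome),
                                   data = data))
    } else {
      rx <- data[[v]] - mean(data[[v]])
      ry <- data[[outcome]] - mean(data[[outcome]])
    }
    stats::cor(rx, ry)
  }, numeric(1))
  r2 <- sm$r.squared
  table <- data.frame(
    beta_normalized = coefs[, "Estimate"],
    se = coefs[, "Std. Error"],
    t = coefs[, "t value"],
    p = coefs[, "Pr(>|t|)"],
    partial_rho = partial_rho,
    row.names = predictors
  )
  structure(
    list(coefficients = table, r_squared = r2,
         adj_r_squared = adjusted_r_squared(r2, n, k),
         f_statistic = f_from_r_squared(r2, n, k),
         df = c(k, n - k - 1),
         p_value = stats::pf(f_from_r_squared(r2, n, k), k, n - k - 1,
                             lower.tail = FALSE),
         n = n, outcome = outcome, predictors = predictors,
         fit_raw = fit_raw, fit_z = fit_z, data = data),
    class = "speech_model"
  )
}

#' Adjusted R-squared
#'
#' `1 - (1 - r2) * (n - 1) / (n - k - 1)`.
#' @param r2 Coefficient of determination.
#' @param n Number of observations.
#' @param k Number of predictors.
#' @return Adjusted R-squared.
#' @export
adjusted_r_squared <- function(r2, n, k) 1 - (1 - r2) * (n - 1) / (n - k - 1)

#' Overall F statistic from R-squared
#'
#' `(r2 / k) / ((1 - r2) / (n - k - 1))` on `(k, n - k - 1)` df.
#' @inheritParams adjusted_r_squared
#' @return F statistic.
#' @export
f_from_r_squared <- function(r2, n, k) (r2 / k) / ((1 - r2) / (n - k - 1))

#' @export
print.speech_model <- function(x, ...) {
  cat(sprintf("Speech-in-noise regression: %s ~ %s (n = %d)\n", x$outcome,
              paste(x$predictors, collapse = " + "), x$n))
  tab <- x$coefficients
  tab[] <- lapply(tab, function(col) signif(col, 3))
  print(tab)
  cat(sprintf("R^2 = %.3f, adjusted R^2 = %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              x$r_squared, x$adj_r_squared, x$df[1], x$df[2], x$f_statistic,
              x$p_value))
  invisible(x)
}

#' Summarize a speech-in-noise regression
#'
#' @param object A `speech_model`.
#' @param ... Unused.
#' @return A list with the coefficient table (normalized beta, SE, t, p,
#'   partial rho) and model-level statistics.
#' @export
summary.speech_model <- function(object, ...) {
  out <- object[c("coefficients", "r_squared", "adj_r_squared", "f_statistic",
                  "df", "p_value", "n")]
  class(out) <- "summary.speech_model"
  out
}

#' @export
print.summary.speech_model <- function(x, ...) {
  print(x$coefficients)
  cat(sprintf("R^2 = %.3f, adjusted R^2 = %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              x$r_squared, x$adj_r_squared, x$df[1], x$df[2], x$f_statistic,
              x$p_value))
  invisible(x)
}

#' @export
coef.speech_model <- function(object, ...) {
  stats::setNames(object$coefficients$beta_normalized,
                  rownames(object$coefficients))
}

#' @export
predict.speech_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    stats::predict(object$fit_raw)
  } else {
    stats::predict(object$fit_raw, newdata = newdata)
  }
}

#' @export
residuals.speech_model <- function(object, ...) stats::resid(object$fit_raw)

#' @export
simulate.speech_model <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$fit_raw, nsim = nsim, seed = seed, ...)
}

#' Partial-residual pair for one predictor
#'
#' Residual of the outcome on the non-focal predictors, paired with either
#' the raw focal predictor or its own residual on the others. The
#' correlation of the residual-residual pair equals the model's partial
#' correlation for the focal predictor.
#'
#' @param object A `speech_model`.
#' @param focal Name of the focal predictor.
#' @param residualize_x Logical; residualize the focal predictor too
#'   (default TRUE, giving the partial-correlation pair).
#' @return Data frame with columns `x` and `outcome_residual`.
#' @export
partial_residual <- function(object, focal, residualize_x = TRUE) {
  stopifnot(inherits(object, "speech_model"))
  if (!focal %in% object$predictors) {
    stop("unknown predictor: ", focal, call. = FALSE)
  }
  others <- setdiff(object$predictors, focal)
  data <- object$data
  if (length(others)) {
    ry <- stats::resid(stats::lm(stats::reformulate(others,
                                                    response = object$outcome),
                                 data = data))
    x <- if (residualize_x) {
      stats::resid(stats::lm(stats::reformulate(others, response = focal),
                             data = data))
    } else {
      data[[focal]]
    }
  } else {
    ry <- data[[object$outcome]] - mean(data[[object$outcome]])
    x <- if (residualize_x) data[[focal]] - mean(data[[focal]]) else data[[focal]]
  }
  data.frame(x = x, outcome_residual = ry)
}

#' Partial-residual plots for a speech model
#'
#' One panel per predictor: outcome residualized on the other predictors
#' against the focal predictor, with the least-squares line.
#'
#' @param x A `speech_model`.
#' @param residualize_x Passed to [partial_residual()].
#' @param ... Further graphical arguments.
#' @export
plot.speech_model <- function(x, residualize_x = TRUE, ...) {
  k <- length(x$predictors)
  old <- graphics::par(mfrow = c(1, k))
  on.exit(graphics::par(old))
  for (v in x$predictors) {
    pr <- partial_residual(x, v, residualize_x = residualize_x)
    graphics::plot(pr$x, pr$outcome_residual, xlab = v,
                   ylab = paste(x$outcome, "residual"), ...)
    graphics::abline(stats::lm(outcome_residual ~ x, data = pr), lty = 2)
  }
  invisible(x)
}
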