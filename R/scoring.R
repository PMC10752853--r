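# Outcome scoring: yes/no signal-detection d-prime for the figure-ground
# task and proportion-correct word scoring for sentence-in-noise tests.

#' Tabulated yes/no outcomes
#'
#' @param hits,misses Counts on figure (signal) trials.
#' @param false_alarms,correct_rejections Counts on ground (noise) trials.
#' @return A list of class `yes_no_counts`.
#' @export
yes_no_counts <- function(hits, misses, false_alarms, correct_rejections) {
  counts <- c(hits, misses, false_alarms, correct_rejections)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(list(hits = hits, misses = misses, false_alarms = false_alarms,
                 correct_rejections = correct_rejections),
            class = "yes_no_counts")
}

#' Yes/no sensitivity d-prime
#'
#' `d' = z(hit rate) - z(false-alarm rate)`. The default log-linear
#' correction adds 0.5 to every cell and 1 to each denominator before
#' computing rates -- always, not only at extreme rates -- which keeps the
#' estimate finite and continuous. `correction = "clip"` instead clips raw
#' rates to `[1/(2N), 1 - 1/(2N)]`; `"none"` uses the raw rates (infinite at
#' perfect performance).
#'
#' @param counts A [yes_no_counts()].
#' @param correction One of `"loglinear"` (default), `"clip"`, `"none"`.
#' @return d-prime in standard-deviation units.
#' @examples
#' dprime_yes_no(yes_no_counts(41, 19, 19, 41), correction = "none")  # 0.954
#' @export
dprime_yes_no <- function(counts, correction = c("loglinear", "clip", "none")) {
  stopifnot(inherits(counts, "yes_no_counts"))
  correction <- match.arg(correction)
  n_sig <- counts$hits + counts$misses
  n_noise <- counts$false_alarms + counts$correct_rejections
  if (n_sig == 0 || n_noise == 0) {
    stop("both signal and noise trials are required for d-prime", call. = FALSE)
  }
  rates <- switch(
    correction,
    loglinear = c((counts$hits + 0.5) / (n_sig + 1),
                  (counts$false_alarms + 0.5) / (n_noise + 1)),
    clip = c(min(max(counts$hits / n_sig, 1 / (2 * n_sig)), 1 - 1 / (2 * n_sig)),
             min(max(counts$false_alarms / n_noise, 1 / (2 * n_noise)),
                 1 - 1 / (2 * n_noise))),
    none = c(counts$hits / n_sig, counts$false_alarms / n_noise)
  )
  stats::qnorm(rates[1]) - stats::qnorm(rates[2])
}

#' Word-level speech score
#'
#' Proportion of correctly repeated words over all presented sentences.
#'
#' @param correct_words Number of words repeated correctly.
#' @param total_words Total words presented; must be positive.
#' @return A list of class `speech_score` with `correct_words`,
#'   `total_words` and `proportion`.
#' @export
score_speech <- function(correct_words, total_words) {
  if (total_words <= 0) stop("total_words must be positive", call. = FALSE)
  if (correct_words < 0 || correct_words > total_words) {
    stop("correct_words must be in [0, total_words]", call. = FALSE)
  }
  structure(list(correct_words = correct_words, total_words = total_words,
                 proportion = correct_words / total_words),
            class = "speech_score")
}

#' Score a figure-ground yes/no session
#'
#' Tabulates the 2x2 outcome table from trial labels and responses and
#' computes d-prime.
#'
#' @param is_figure Logical vector of trial labels (TRUE = figure present).
#' @param response_yes Logical vector of "figure detected" responses.
#' @param correction Passed to [dprime_yes_no()].
#' @return A list with `counts` ([yes_no_counts()]) and `dprime`.
#' @export
score_sfg_session <- function(is_figure, response_yes,
                              correction = "loglinear") {
  if (length(is_figure) != length(response_yes)) {
    stop("labels and responses must have equal length", call. = FALSE)
  }
  counts <- yes_no_counts(
    hits = sum(is_figure & response_yes),
    misses = sum(is_figure & !response_yes),
    false_alarms = sum(!is_figure & response_yes),
    correct_rejections = sum(!is_figure & !response_yes)
  )
  list(counts = counts, dprime = dprime_yes_no(counts, correction))
}
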