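#' Drop physiologically extreme height and weight values
#'
#' Weights below 80 lb or above 500 lb and heights below 48 in or above
#' 95 in are removed (strict inequalities: boundary values are retained).
#'
#' @param measurements data frame with columns `kind`
#'   (`"height"`/`"weight"`) and `value`; other columns pass through.
#' @return The filtered data frame.
#' @export
filter_extremes <- function(measurements) {
  if (nrow(measurements) == 0) return(measurements)
  v <- measurements$value
  k <- measurements$kind
  drop <- (k == "weight" & (v < 80 | v > 500)) |
          (k == "height" & (v < 48 | v > 95))
  measurements[!drop, , drop = FALSE]
}

#' Select one height per participant per source
#'
#' Uses the modal value across a participant's height measurements; when
#' all values are distinct, the first recorded height is used. A modal tie
#' is broken toward the earliest-dated modal value, consistent with the
#' all-distinct fallback.
#'
#' @param values numeric heights (extremes already filtered).
#' @param dates measurement dates, same length.
#' @return The selected height, or `NA_real_` when no values remain.
#' @export
select_height <- function(values, dates) {
  if (length(values) == 0) return(NA_real_)
  dates <- as.Date(dates)
  ord <- order(dates)
  values <- values[ord]
  dates <- dates[ord]
  counts <- table(values)
  if (max(counts) == 1) return(values[1])
  modal <- as.numeric(names(counts)[counts == max(counts)])
  # earliest-dated among the tied modal values
  values[values %in% modal][1]
}

#' Select the weight paired with a survey
#'
#' Among weights dated within the window of the survey date, returns the
#' one recorded closest to the survey; an equidistant before/after tie is
#' broken toward the earlier (pre-survey) measurement.
#'
#' @param values numeric weights (extremes already filtered).
#' @param dates measurement dates, same length.
#' @param survey_date the survey date.
#' @param window_days half-width of the eligibility window in days
#'   (default 365: "within 1 year", symmetric and inclusive).
#' @param one_sided if `TRUE`, only measurements on or before the survey
#'   date are eligible.
#' @return The selected weight, or `NA_real_` when none qualifies.
#' @export
select_weight <- function(values, dates, survey_date, window_days = 365,
                          one_sided = FALSE) {
  if (length(values) == 0) return(NA_real_)
  dates <- as.Date(dates)
  survey_date <- as.Date(survey_date)
  delta <- as.numeric(dates - survey_date)
  ok <- abs(delta) <= window_days
  if (one_sided) ok <- ok & delta <= 0
  if (!any(ok)) return(NA_real_)
  values <- values[ok]; delta <- delta[ok]
  best <- min(abs(delta))
  cand <- which(abs(delta) == best)
  if (length(cand) > 1) cand <- cand[order(delta[cand])][1]  # earlier first
  values[cand]
}

#' Bland-Altman agreement summary
#'
#' Differences are record minus survey. Limits of agreement are the mean
#' difference plus/minus 2 sample standard deviations (not 1.96), and the
#' outside proportion counts pairs strictly beyond either limit.
#'
#' @param ehr,survey paired numeric vectors (record and self-reported
#'   values); pairs with a missing member are dropped.
#' @return An object of class `bland_altman`: list with `n`,
#'   `mean_difference`, `sd_difference`, `lower_limit`, `upper_limit`,
#'   `prop_outside`, and the per-pair `differences` and `means` (for
#'   plotting).
#' @export
bland_altman <- function(ehr, survey) {
  if (length(ehr) != length(survey)) {
    stop("`ehr` and `survey` must have the same length", call. = FALSE)
  }
  keep <- !is.na(ehr) & !is.na(survey)
  ehr <- ehr[keep]; survey <- survey[keep]
  if (length(ehr) < 2) {
    stop("Bland-Altman requires at least 2 complete pairs", call. = FALSE)
  }
  d <- ehr - survey
  m <- mean(d)
  s <- stats::sd(d)
  lo <- m - 2 * s
  hi <- m + 2 * s
  structure(
    list(n = length(d), mean_difference = m, sd_difference = s,
         lower_limit = lo, upper_limit = hi,
         prop_outside = mean(d < lo | d > hi),
         differences = d, means = (ehr + survey) / 2),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: n = %d pairs\n  mean difference (record - survey) = %.3f (SD %.3f)\n  limits of agreement (mean +/- 2 SD): [%.3f, %.3f]\n  %.1f%% of pairs outside the limits\n",
    x$n, x$mean_difference, x$sd_difference, x$lower_limit, x$upper_limit,
    100 * x$prop_outside))
  invisible(x)
}

#' Plot a Bland-Altman summary
#'
#' Scatter of pair means against differences with the mean-difference and
#' +/- 2 SD reference lines. Requires ggplot2.
#'
#' @param x a [bland_altman()] summary.
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(x, ...) {
  stopifnot(inherits(x, "bland_altman"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- data.frame(mean = x$means, difference = x$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = difference)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(yintercept = x$mean_difference) +
    ggplot2::geom_hline(yintercept = c(x$lower_limit, x$upper_limit),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of record and survey values",
                  y = "Record - survey difference")
}
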