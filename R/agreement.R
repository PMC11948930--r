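#' Two-by-two concordance table
#'
#' Cross-classifies paired case statuses from two observation channels
#' (survey self-report as rows, medical record as columns). Pairs in which
#' either status is missing are dropped before counting; `a` counts
#' concordant positives, `d` concordant negatives, `b` survey-only
#' positives and `c` record-only positives.
#'
#' @param survey,ehr character vectors of equal length with values
#'   `"positive"`, `"negative"` or `NA` (missing). Factors are accepted.
#' @return An object of class `two_by_two`: a list with integer counts
#'   `a`, `b`, `c`, `d`, the retained total `n`, and `n_dropped` (pairs
#'   excluded for missingness).
#' @seealso [agreement_stats()] for the statistics computed from the table.
#' @export
build_table <- function(survey, ehr) {
  survey <- as.character(survey)
  ehr <- as.character(ehr)
  if (length(survey) != length(ehr)) {
    stop("`survey` and `ehr` must have the same length", call. = FALSE)
  }
  chk <- function(x, nm) {
    bad <- !is.na(x) & !x %in% c("positive", "negative")
    if (any(bad)) {
      stop(sprintf("`%s` contains values other than positive/negative/NA: %s",
                   nm, paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
    }
  }
  chk(survey, "survey"); chk(ehr, "ehr")
  keep <- !is.na(survey) & !is.na(ehr)
  if (!any(keep)) {
    stop("all pairs have a missing status in at least one source", call. = FALSE)
  }
  s <- survey[keep] == "positive"
  e <- ehr[keep] == "positive"
  two_by_two(
    a = sum(s & e), b = sum(s & !e), c = sum(!s & e), d = sum(!s & !e),
    n_dropped = sum(!keep)
  )
}

#' Construct a two-by-two table from counts
#'
#' @param a,b,c,d nonnegative cell counts: `a` = both positive,
#'   `b` = survey-positive only, `c` = record-positive only,
#'   `d` = both negative.
#' @param n_dropped pairs excluded for missingness (bookkeeping only).
#' @return A `two_by_two` object.
#' @export
two_by_two <- function(a, b, c, d, n_dropped = 0L) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be nonnegative integers", call. = FALSE)
  }
  structure(
    list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
         d = as.integer(d), n = as.integer(a + b + c + d),
         n_dropped = as.integer(n_dropped)),
    class = "two_by_two"
  )
}

#' @export
print.two_by_two <- function(x, ...) {
  cat("2x2 concordance table (rows: survey, cols: record)\n")
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("survey+", "survey-"), c("record+", "record-")))
  print(m)
  cat(sprintf("N = %d retained, %d dropped for missing status\n",
              x$n, x$n_dropped))
  invisible(x)
}

#' Positive agreement (proportion of specific positive agreement)
#'
#' Computed as `2a / [N + (a - d)]`, which equals `2a / (2a + b + c)`:
#' the chance-uncorrected agreement restricted to the positive cells.
#'
#' @param t a `two_by_two` table.
#' @return A fraction in \[0, 1\], or `NA_real_` when undefined
#'   (no positives in either source: a = b = c = 0).
#' @export
positive_agreement <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  denom <- t$n + (t$a - t$d)
  if (denom <= 0) return(NA_real_)
  2 * t$a / denom
}

#' Negative agreement (proportion of specific negative agreement)
#'
#' Computed as `2d / [N - (a - d)]`, which equals `2d / (2d + b + c)`.
#'
#' @inheritParams positive_agreement
#' @return A fraction in \[0, 1\], or `NA_real_` when undefined.
#' @export
negative_agreement <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  denom <- t$n - (t$a - t$d)
  if (denom <= 0) return(NA_real_)
  2 * t$d / denom
}

#' Youden's J for survey self-report against the medical record
#'
#' The medical record is the reference standard: sensitivity is
#' `a / (a + c)` (the proportion of record-positive participants who
#' self-report) and specificity is `d / (b + d)`. J = sensitivity +
#' specificity - 1, a prevalence-independent concordance index in
#' \[-1, 1\].
#'
#' @inheritParams positive_agreement
#' @return J, or `NA_real_` when either record margin is empty.
#' @export
youden_j <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  if ((t$a + t$c) == 0 || (t$b + t$d) == 0) return(NA_real_)
  t$a / (t$a + t$c) + t$d / (t$b + t$d) - 1
}

#' All agreement statistics for one table
#'
#' @inheritParams positive_agreement
#' @return A one-row tibble: `n`, survey and record prevalence,
#'   `positive_agreement`, `negative_agreement`, `sensitivity`,
#'   `specificity`, `youden_j`. Undefined statistics are `NA`, never 0.
#' @export
agreement_stats <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  sens <- if ((t$a + t$c) > 0) t$a / (t$a + t$c) else NA_real_
  spec <- if ((t$b + t$d) > 0) t$d / (t$b + t$d) else NA_real_
  tibble::tibble(
    n = t$n,
    n_survey_pos = t$a + t$b,
    n_ehr_pos = t$a + t$c,
    survey_prevalence = (t$a + t$b) / t$n,
    ehr_prevalence = (t$a + t$c) / t$n,
    positive_agreement = positive_agreement(t),
    negative_agreement = negative_agreement(t),
    sensitivity = sens,
    specificity = spec,
    youden_j = if (is.na(sens) || is.na(spec)) NA_real_ else sens + spec - 1
  )
}

#' Round half away from zero at a fixed number of decimals
#'
#' Matches the rounding convention of printed tables (half-up), unlike
#' [round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny nudge guards against representation error in values that are
  # exactly on the .5 boundary in decimal (e.g. 31.45)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Reconstruct 2x2 cell counts from printed marginals and positive agreement
#'
#' Printed concordance tables typically report only the total `N`, the two
#' positive margins and the agreement statistics. Because positive
#' agreement depends on the cells only through `a` (given the margins),
#' every integer `a` whose positive agreement rounds (half-up, one
#' decimal, as a percentage) to the printed value yields a candidate
#' table. This inverts that relationship, enabling internal-consistency
#' checks of printed tables.
#'
#' @param n total participants.
#' @param n_survey,n_ehr printed positive counts for survey and record.
#' @param pa_percent printed positive agreement, in percent at one
#'   decimal (e.g. `56.3`).
#' @return A list of `two_by_two` candidate tables, one per consistent
#'   integer `a`.
#' @export
reconstruct_cells <- function(n, n_survey, n_ehr, pa_percent) {
  if (n_survey > n || n_ehr > n) {
    stop("margins exceed the table total", call. = FALSE)
  }
  a_max <- min(n_survey, n_ehr)
  a_min <- max(0L, n_survey + n_ehr - n)
  a_all <- seq.int(a_min, a_max)
  denom <- n_survey + n_ehr
  pa <- if (denom > 0) 100 * 2 * a_all / denom else rep(NA_real_, length(a_all))
  keep <- !is.na(pa) & round_half_up(pa, 1) == pa_percent
  a_keep <- a_all[keep]
  if (length(a_keep) == 0) {
    stop(sprintf(
      "no integer dual-positive count is consistent with PA = %.1f%% given margins %d/%d of %d",
      pa_percent, n_survey, n_ehr, n), call. = FALSE)
  }
  lapply(a_keep, function(a) {
    two_by_two(a = a, b = n_survey - a, c = n_ehr - a,
               d = n - n_survey - n_ehr + a)
  })
}

#' Statistics reconstructed from printed marginals and positive agreement
#'
#' Reconstructs the candidate tables with [reconstruct_cells()] and
#' reports negative agreement, sensitivity, specificity and Youden's J
#' from the representative candidate — the integer `a` whose exact
#' positive agreement lies closest to the printed (rounded) value, i.e.
#' the midpoint of the rounding interval. The full candidate ranges are
#' returned alongside so the stability of the rounded statistics across
#' candidates can be checked.
#'
#' @inheritParams reconstruct_cells
#' @return A one-row tibble: `a` (representative dual-positive count),
#'   `n_candidates`, `negative_agreement_percent`, `youden_j`,
#'   `sensitivity`, `specificity` (representative candidate, unrounded
#'   except where noted: NA% rounded half-up to one decimal and J to two,
#'   the printed precisions), plus `na_percent_min`/`max` and
#'   `j_min`/`j_max` (rounded ranges across all candidates).
#' @export
reconstruct_statistics <- function(n, n_survey, n_ehr, pa_percent) {
  cand <- reconstruct_cells(n, n_survey, n_ehr, pa_percent)
  a <- vapply(cand, `[[`, 0L, "a")
  pa_exact <- 100 * 2 * a / (n_survey + n_ehr)
  rep_i <- which.min(abs(pa_exact - pa_percent))
  na_r <- vapply(cand, function(t) round_half_up(100 * negative_agreement(t), 1), 0)
  j_r <- vapply(cand, function(t) round_half_up(youden_j(t), 2), 0)
  t <- cand[[rep_i]]
  st <- agreement_stats(t)
  tibble::tibble(
    a = t$a, n_candidates = length(cand),
    negative_agreement_percent = na_r[rep_i],
    youden_j = j_r[rep_i],
    sensitivity = st$sensitivity, specificity = st$specificity,
    na_percent_min = min(na_r), na_percent_max = max(na_r),
    j_min = min(j_r), j_max = max(j_r))
}

#' Check a printed concordance table row for internal consistency
#'
#' Reconstructs all candidate cell configurations from the printed
#' marginals and positive agreement, recomputes negative agreement and
#' Youden's J for each, and compares with the printed values at printed
#' precision (one decimal for percentages, two for J).
#'
#' @inheritParams reconstruct_cells
#' @param na_percent printed negative agreement (percent, one decimal).
#' @param j printed Youden's J (two decimals).
#' @return A list: `candidates` (the reconstructed tables), `na_values`
#'   and `j_values` (rounded recomputed statistics per candidate), and
#'   `consistent` (TRUE if some candidate reproduces both printed values).
#' @export
check_printed_row <- function(n, n_survey, n_ehr, pa_percent, na_percent, j) {
  cand <- reconstruct_cells(n, n_survey, n_ehr, pa_percent)
  na_vals <- vapply(cand, function(t) round_half_up(100 * negative_agreement(t), 1), 0)
  j_vals <- vapply(cand, function(t) round_half_up(youden_j(t), 2), 0)
  list(
    candidates = cand,
    na_values = na_vals,
    j_values = j_vals,
    consistent = any(na_vals == na_percent & j_vals == j)
  )
}
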