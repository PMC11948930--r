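#' PHQ problem-drinking flag from the five risky-drinking items
#'
#' Probable problem drinking is positive endorsement of at least one of
#' the five items. All five "no" gives a negative flag; no "yes" with any
#' missing item gives a missing flag (an unanswered item could have been
#' the endorsement).
#'
#' @param items character vector of exactly five answers:
#'   `"yes"`/`"no"`/`NA`.
#' @return `"yes"`, `"no"` or `"missing"`.
#' @export
phq_problem_drinking <- function(items) {
  if (length(items) != 5) {
    stop("the PHQ problem-drinking screen has exactly 5 items", call. = FALSE)
  }
  items <- as.character(items)
  bad <- !is.na(items) & !items %in% c("yes", "no")
  if (any(bad)) stop("items must be yes/no/NA", call. = FALSE)
  if (any(items == "yes", na.rm = TRUE)) return("yes")
  if (!anyNA(items) && all(items == "no")) return("no")
  "missing"
}

#' AUDIT-C alcohol-misuse flag
#'
#' Sex-specific screening cutoffs on the 0-12 AUDIT-C total: misuse at a
#' score of 3 or more for women, 4 or more for men.
#'
#' @param score integer AUDIT-C total in \[0, 12\] (vectorized).
#' @param sex `"female"` or `"male"` (vectorized, recycled).
#' @return `"yes"`/`"no"` character vector.
#' @export
auditc_misuse <- function(score, sex) {
  sex <- rep_len(as.character(sex), length(score))
  if (any(is.na(score)) || any(score < 0 | score > 12 | score != round(score))) {
    stop("AUDIT-C scores must be integers in [0, 12]", call. = FALSE)
  }
  if (!all(sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'", call. = FALSE)
  }
  cutoff <- ifelse(sex == "female", 3, 4)
  ifelse(score >= cutoff, "yes", "no")
}

#' Select the AUDIT-C assessment paired with a survey
#'
#' The assessment closest in time strictly prior to the survey date; when
#' several assessments fall on that day, the highest score is used.
#'
#' @param scores integer AUDIT-C totals.
#' @param dates assessment dates, same length.
#' @param survey_date the completed survey date.
#' @return The selected score, or `NA_real_` when no prior assessment
#'   exists.
#' @export
select_auditc <- function(scores, dates, survey_date) {
  if (length(scores) == 0) return(NA_real_)
  dates <- as.Date(dates)
  prior <- dates < as.Date(survey_date)
  if (!any(prior)) return(NA_real_)
  scores <- scores[prior]; dates <- dates[prior]
  latest <- max(dates)
  max(scores[dates == latest])
}

#' Ever-smoker flag from the lifetime 100-cigarettes survey item
#'
#' Carry-forward across waves: a "yes" at any wave classifies the
#' participant as an ever smoker; "no" at some wave with no "yes" is
#' never-smoker; all-missing is missing.
#'
#' @param answers character vector over waves: `"yes"`/`"no"`/`NA`.
#' @return `"yes"`, `"no"` or `"missing"`.
#' @export
survey_ever_smoker <- function(answers) {
  if (length(answers) == 0) {
    stop("at least one survey wave is required", call. = FALSE)
  }
  answers <- as.character(answers)
  if (any(answers == "yes", na.rm = TRUE)) return("yes")
  if (any(answers == "no", na.rm = TRUE)) return("no")
  "missing"
}

#' Select the health-factors smoking assessment paired with a survey
#'
#' The assessment with the smallest absolute distance to the survey date,
#' on either side; an equidistant tie is broken toward the earlier record.
#'
#' @param statuses character vector of recorded smoking statuses.
#' @param dates assessment dates, same length.
#' @param survey_date the survey date.
#' @return The selected status, or `NA_character_` when there are no
#'   assessments.
#' @export
select_ehr_smoking <- function(statuses, dates, survey_date) {
  if (length(statuses) == 0) return(NA_character_)
  dates <- as.Date(dates)
  delta <- as.numeric(dates - as.Date(survey_date))
  best <- min(abs(delta))
  cand <- which(abs(delta) == best)
  if (length(cand) > 1) cand <- cand[order(delta[cand])][1]
  as.character(statuses[cand])
}
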