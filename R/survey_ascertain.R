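#' Classify a participant-condition across survey waves (carry-forward)
#'
#' A "yes" at any wave makes the participant a positive case from that
#' wave onward (a later "no" does not revoke it); the diagnosis date is
#' the survey date of the first "yes". A participant who never answers
#' "yes" but answers "no" at some wave is negative; one with missing
#' answers at every wave is missing.
#'
#' @param answers character vector over waves, in wave order: `"yes"`,
#'   `"no"` or `NA` (missing).
#' @param survey_dates `Date` vector, same length, nondecreasing.
#' @param participant_id,condition_id identifiers carried into the result.
#' @return A `case_status` with status `positive`/`negative`/`missing`;
#'   positive statuses carry the first-self-report survey date.
#' @export
classify_survey_case <- function(answers, survey_dates,
                                 participant_id = NA, condition_id = NA) {
  if (length(answers) == 0) {
    stop("at least one survey wave is required", call. = FALSE)
  }
  if (length(answers) != length(survey_dates)) {
    stop("`answers` and `survey_dates` must have the same length", call. = FALSE)
  }
  answers <- as.character(answers)
  bad <- !is.na(answers) & !answers %in% c("yes", "no")
  if (any(bad)) {
    stop("answers must be yes/no/NA", call. = FALSE)
  }
  survey_dates <- as.Date(survey_dates)
  if (is.unsorted(survey_dates, na.rm = TRUE)) {
    stop("survey dates must be nondecreasing in wave order", call. = FALSE)
  }
  first_yes <- match("yes", answers)
  if (!is.na(first_yes)) {
    case_status(participant_id, condition_id, "positive",
                diagnosis_date = survey_dates[first_yes])
  } else if (any(answers == "no", na.rm = TRUE)) {
    case_status(participant_id, condition_id, "negative")
  } else {
    case_status(participant_id, condition_id, "missing")
  }
}

#' Carried-forward status as of a given wave
#'
#' The classification using only waves up to and including `wave`. Once
#' positive, the status stays positive at every later wave.
#'
#' @inheritParams classify_survey_case
#' @param wave wave index (1-based) into `answers`.
#' @return `"positive"`, `"negative"` or `"missing"`.
#' @export
status_as_of <- function(answers, survey_dates, wave) {
  if (wave < 1 || wave > length(answers)) {
    stop("unknown wave index", call. = FALSE)
  }
  classify_survey_case(answers[seq_len(wave)],
                       survey_dates[seq_len(wave)])$status
}

#' Cohort-scale survey case classification
#'
#' Applies carry-forward classification to every participant for one
#' condition column of a long survey table.
#'
#' @param surveys survey table: one row per participant-wave, columns
#'   `participant_id`, `wave`, `survey_date`, plus one column per
#'   condition coded 1 (yes) / 0 (no) / `NA` (missing; a wholly
#'   unanswered wave simply has `NA` in every condition column).
#' @param condition_id name of the condition column to classify.
#' @return A tibble: `participant_id`, `status`, `diagnosis_date` (first
#'   self-report survey date for positives), `last_survey_date` (latest
#'   wave date with a non-missing answer for this condition; `NA` when
#'   all waves are missing).
#' @export
classify_survey_cohort <- function(surveys, condition_id) {
  if (!condition_id %in% names(surveys)) {
    stop("no survey column for condition: ", condition_id, call. = FALSE)
  }
  df <- tibble::tibble(
    participant_id = surveys$participant_id,
    wave = surveys$wave,
    survey_date = as.Date(surveys$survey_date),
    answer = surveys[[condition_id]]
  )
  df <- df[order(df$participant_id, df$wave), ]
  ids <- unique(df$participant_id)

  # rows are wave-ordered within participant and wave dates are
  # nondecreasing, so the first "yes" row per participant carries the
  # first-self-report date and the last non-missing row the last
  # completed-answer date
  yes <- df[which(df$answer == 1), ]
  first_yes <- yes[!duplicated(yes$participant_id), ]
  nonmiss <- df[!is.na(df$answer), ]
  last_ans <- nonmiss[!duplicated(nonmiss$participant_id, fromLast = TRUE), ]
  no_ids <- unique(df$participant_id[which(df$answer == 0)])

  i_yes <- match(ids, first_yes$participant_id)
  status <- ifelse(!is.na(i_yes), "positive",
                   ifelse(ids %in% no_ids, "negative", "missing"))
  tibble::tibble(
    participant_id = ids,
    status = status,
    diagnosis_date = first_yes$survey_date[i_yes],
    last_survey_date = last_ans$survey_date[match(ids, last_ans$participant_id)]
  )
}
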