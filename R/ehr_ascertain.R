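#' Normalize a diagnosis or procedure code
#'
#' Upper-cases, strips whitespace and removes the decimal point, the usual
#' canonical form for comparing ICD codes across sources ("250.00" and
#' "25000" are the same code). Idempotent.
#'
#' @param code character vector of raw code strings.
#' @return Normalized character vector.
#' @export
normalize_code <- function(code) {
  code <- as.character(code)
  if (any(is.na(code)) || any(!nzchar(trimws(code)))) {
    stop("codes must be non-empty strings", call. = FALSE)
  }
  gsub(".", "", toupper(gsub("\\s+", "", code)), fixed = TRUE)
}

#' Default code-eligibility window
#'
#' Fiscal-year 1999 start through 2020-09-18, the period over which coded
#' encounters are eligible for case ascertainment.
#'
#' @param start,end window bounds as `Date` (or coercible).
#' @return A list with `start` and `end` dates, class `observation_window`.
#' @export
observation_window <- function(start = as.Date("1999-10-01"),
                               end = as.Date("2020-09-18")) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || start >= end) {
    stop("window start must precede window end", call. = FALSE)
  }
  structure(list(start = start, end = end), class = "observation_window")
}

#' Condition code set
#'
#' The set of diagnosis/procedure codes that define one condition. Codes
#' are normalized on construction; matching is per-entry `prefix`
#' (default, so truncated parent codes match their children) or `exact`.
#'
#' @param condition_id condition identifier.
#' @param code character vector of code patterns.
#' @param code_system character vector (recycled): `"ICD9"`, `"ICD10"` or
#'   `"CPT"`.
#' @param match_mode `"prefix"` or `"exact"` (recycled).
#' @param exclude optional character vector of code patterns; encounter
#'   codes matching any of them (prefix, after normalization) never count
#'   for this condition even if an entry matches (code-exclusion
#'   sensitivity analyses).
#' @return A `condition_codeset` object (tibble of normalized entries plus
#'   the condition id and exclusions).
#' @export
condition_codeset <- function(condition_id, code, code_system = "ICD10",
                              match_mode = "prefix", exclude = character(0)) {
  if (length(code) < 1) stop("a code set needs at least one entry", call. = FALSE)
  code_system <- rep_len(toupper(code_system), length(code))
  match_mode <- rep_len(match_mode, length(code))
  if (!all(code_system %in% c("ICD9", "ICD10", "CPT"))) {
    stop("code_system must be ICD9, ICD10 or CPT", call. = FALSE)
  }
  if (!all(match_mode %in% c("prefix", "exact"))) {
    stop("match_mode must be 'prefix' or 'exact'", call. = FALSE)
  }
  structure(
    list(condition_id = as.character(condition_id),
         entries = tibble::tibble(
           code_system = code_system,
           code = normalize_code(code),
           match_mode = match_mode),
         exclude = if (length(exclude) > 0) normalize_code(exclude)
                   else character(0)),
    class = "condition_codeset"
  )
}

#' Read condition code sets from a delimited file
#'
#' Expected columns: `condition_id`, `code_system`, `code`, and optionally
#' `match_mode` (default `prefix`).
#'
#' @param path file path (comma-delimited, header row).
#' @return A named list of `condition_codeset` objects, one per condition.
#' @export
read_code_sets <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("condition_id", "code_system", "code")
  if (!all(req %in% names(df))) {
    stop("code-set file must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!"match_mode" %in% names(df)) df$match_mode <- "prefix"
  out <- lapply(split(df, df$condition_id), function(g) {
    condition_codeset(g$condition_id[1], g$code, g$code_system, g$match_mode)
  })
  out[order(names(out))]
}

#' Match a code set against encounter codes
#'
#' Returns which of the supplied codes (any diagnostic position) match the
#' code set, after normalization, under each entry's match mode.
#'
#' @param codes character vector of raw codes.
#' @param code_systems character vector, same length.
#' @param codeset a [condition_codeset()].
#' @return Logical vector, `TRUE` where the code matches.
#' @export
match_codes <- function(codes, code_systems, codeset) {
  stopifnot(inherits(codeset, "condition_codeset"))
  if (length(codes) == 0) return(logical(0))
  norm <- normalize_code(codes)
  sys <- toupper(as.character(code_systems))
  hit <- logical(length(norm))
  e <- codeset$entries
  for (i in seq_len(nrow(e))) {
    same_sys <- sys == e$code_system[i]
    if (e$match_mode[i] == "prefix") {
      hit <- hit | (same_sys & startsWith(norm, e$code[i]))
    } else {
      hit <- hit | (same_sys & norm == e$code[i])
    }
  }
  for (ex in codeset$exclude) {
    hit <- hit & !startsWith(norm, ex)
  }
  hit
}

#' Matched codes on one encounter record
#'
#' @param record a one-encounter data frame (or list) with elements
#'   `code`, `code_system` (vectors over the record's diagnostic
#'   positions).
#' @param codeset a [condition_codeset()].
#' @return Character vector of the record's codes that match (possibly
#'   empty).
#' @export
match_condition <- function(record, codeset) {
  as.character(record$code)[match_codes(record$code, record$code_system, codeset)]
}

case_status <- function(participant_id, condition_id, status,
                        diagnosis_date = as.Date(NA),
                        criterion = NA_character_, scope = NA_character_) {
  if (status == "positive" && is.na(diagnosis_date)) {
    stop("a positive case must carry a diagnosis date", call. = FALSE)
  }
  if (status != "positive") diagnosis_date <- as.Date(NA)
  structure(
    list(participant_id = participant_id, condition_id = condition_id,
         status = status, diagnosis_date = diagnosis_date,
         criterion = criterion, scope = scope),
    class = "case_status"
  )
}

#' @export
print.case_status <- function(x, ...) {
  cat(sprintf("case_status: participant %s, condition %s -> %s%s\n",
              x$participant_id, x$condition_id, x$status,
              if (x$status == "positive")
                paste0(" (diagnosed ", format(x$diagnosis_date), ")") else ""))
  invisible(x)
}

# matching in-window rows of one participant's encounter table; optionally
# restricted to records strictly before a reference date with
# personal-history codes excluded
qualifying_rows <- function(records, codeset, window,
                            reference_date = NULL) {
  stopifnot(inherits(window, "observation_window"))
  date <- as.Date(records$event_date)
  keep <- date >= window$start & date <= window$end
  if (!is.null(reference_date)) {
    if (is.na(as.Date(reference_date))) {
      stop("temporal restriction requires a reference date", call. = FALSE)
    }
    keep <- keep & date < as.Date(reference_date)
    ph <- records$personal_history
    if (!is.null(ph)) keep <- keep & !(as.logical(ph) %in% TRUE)
  }
  keep <- keep & match_codes(records$code, records$code_system, codeset)
  records[which(keep), , drop = FALSE]
}

#' Ascertain a case under sensitive criteria
#'
#' A participant is positive when at least one matching code, in any
#' diagnostic position, appears on any in-window inpatient or outpatient
#' record; the diagnosis date is the earliest matching encounter or
#' admission date.
#'
#' @param records one participant's encounter rows: a data frame with
#'   columns `participant_id`, `setting` (`inpatient`/`outpatient`),
#'   `event_date`, `code`, `code_system`, and optionally
#'   `personal_history`.
#' @param codeset a [condition_codeset()].
#' @param window an [observation_window()].
#' @param reference_date optional date; when supplied only records
#'   strictly before it count and personal-history codes are excluded
#'   (temporally restricted analysis).
#' @return A `case_status`.
#' @export
ascertain_sensitive <- function(records, codeset, window = observation_window(),
                                reference_date = NULL) {
  pid <- if (nrow(records) > 0) records$participant_id[1] else NA
  q <- qualifying_rows(records, codeset, window, reference_date)
  if (nrow(q) == 0) {
    return(case_status(pid, codeset$condition_id, "negative",
                       criterion = "sensitive"))
  }
  case_status(pid, codeset$condition_id, "positive",
              diagnosis_date = min(as.Date(q$event_date)),
              criterion = "sensitive")
}

#' Ascertain a case under specific criteria
#'
#' Positive requires at least one matching in-window inpatient record, or
#' matching outpatient records on at least two distinct event dates (the
#' claims "rule of two"; two codes within a single visit do not qualify
#' unless `distinct_dates = FALSE`). The diagnosis date is the earliest
#' matching date among qualifying records.
#'
#' @inheritParams ascertain_sensitive
#' @param distinct_dates require the two outpatient codes to fall on
#'   distinct event dates (default `TRUE`).
#' @return A `case_status`.
#' @export
ascertain_specific <- function(records, codeset, window = observation_window(),
                               reference_date = NULL, distinct_dates = TRUE) {
  pid <- if (nrow(records) > 0) records$participant_id[1] else NA
  q <- qualifying_rows(records, codeset, window, reference_date)
  inpt <- q[q$setting == "inpatient", , drop = FALSE]
  outpt <- q[q$setting == "outpatient", , drop = FALSE]
  out_n <- if (distinct_dates) length(unique(as.Date(outpt$event_date)))
           else nrow(outpt)
  if (nrow(inpt) == 0 && out_n < 2) {
    return(case_status(pid, codeset$condition_id, "negative",
                       criterion = "specific"))
  }
  dates <- as.Date(c(inpt$event_date,
                     if (out_n >= 2) outpt$event_date))
  case_status(pid, codeset$condition_id, "positive",
              diagnosis_date = min(dates), criterion = "specific")
}

#' Temporally restricted ascertainment
#'
#' Applies the chosen criterion using only records strictly before the
#' reference date (a same-day code cannot be shown to precede it), with
#' personal-history codes excluded because they carry no diagnosis date.
#'
#' @inheritParams ascertain_specific
#' @param criterion `"sensitive"` or `"specific"`.
#' @param reference_date the anchoring date (e.g. the survey date of first
#'   self-report); required.
#' @return A `case_status`.
#' @export
restrict_prior <- function(records, codeset, window = observation_window(),
                           reference_date, criterion = c("sensitive", "specific"),
                           distinct_dates = TRUE) {
  criterion <- match.arg(criterion)
  if (missing(reference_date) || is.na(as.Date(reference_date))) {
    stop("temporal restriction requires a reference date", call. = FALSE)
  }
  if (criterion == "sensitive") {
    ascertain_sensitive(records, codeset, window, reference_date)
  } else {
    ascertain_specific(records, codeset, window, reference_date, distinct_dates)
  }
}

#' Merge case statuses from two record sources
#'
#' Positive if either source is positive, with the earliest available
#' diagnosis date; negative only when both are negative.
#'
#' @param x,y `case_status` objects for the same participant, condition
#'   and criterion (e.g. VHA and MDR).
#' @return A merged `case_status` with scope `"combined"`.
#' @export
merge_sources <- function(x, y) {
  stopifnot(inherits(x, "case_status"), inherits(y, "case_status"))
  if (!identical(x$condition_id, y$condition_id) ||
      !identical(x$criterion, y$criterion)) {
    stop("cannot merge case statuses for different conditions or criteria",
         call. = FALSE)
  }
  if (x$status == "positive" || y$status == "positive") {
    dates <- c(x$diagnosis_date, y$diagnosis_date)
    case_status(x$participant_id, x$condition_id, "positive",
                diagnosis_date = min(dates, na.rm = TRUE),
                criterion = x$criterion, scope = "combined")
  } else {
    case_status(x$participant_id, x$condition_id, "negative",
                criterion = x$criterion, scope = "combined")
  }
}

#' Cohort-scale EHR case ascertainment
#'
#' Vectorized ascertainment across all participants and one condition.
#' Participants absent from the encounter table are negative (they have no
#' qualifying codes).
#'
#' @param encounters encounter table for the whole cohort (columns as in
#'   [ascertain_sensitive()], plus `source` with values `VHA`/`MDR`;
#'   purchased-care rows should be ingested with source `VHA`).
#' @param codeset a [condition_codeset()].
#' @param participant_ids vector of all cohort ids (defines the output
#'   rows).
#' @param criterion `"sensitive"` or `"specific"`.
#' @param scope `"vha"` (VHA rows only) or `"combined"` (VHA + MDR).
#' @param window an [observation_window()].
#' @param reference_dates optional named vector/`Date` of per-participant
#'   reference dates (names = participant ids) for temporally restricted
#'   analysis; participants with `NA` reference dates get status `NA`
#'   (excluded from restricted comparisons).
#' @param distinct_dates see [ascertain_specific()].
#' @return A tibble: `participant_id`, `status` (`positive`/`negative` or
#'   `NA`), `diagnosis_date`.
#' @export
ascertain_ehr_cohort <- function(encounters, codeset, participant_ids,
                                 criterion = c("sensitive", "specific"),
                                 scope = c("vha", "combined"),
                                 window = observation_window(),
                                 reference_dates = NULL,
                                 distinct_dates = TRUE) {
  criterion <- match.arg(criterion)
  scope <- match.arg(scope)
  enc <- encounters
  if (scope == "vha") enc <- enc[enc$source == "VHA", , drop = FALSE]

  date <- as.Date(enc$event_date)
  keep <- date >= window$start & date <= window$end &
    match_codes(enc$code, enc$code_system, codeset)
  restricted <- !is.null(reference_dates)
  if (restricted) {
    ref <- as.Date(reference_dates)[match(enc$participant_id,
                                          names(reference_dates))]
    keep <- keep & !is.na(ref) & date < ref
    ph <- enc$personal_history
    if (!is.null(ph)) keep <- keep & !(as.logical(ph) %in% TRUE)
  }
  m <- enc[which(keep), c("participant_id", "setting", "event_date")]
  m$event_date <- as.Date(m$event_date)

  first_date_by_id <- function(df) {
    if (nrow(df) == 0) {
      return(tibble::tibble(participant_id = df$participant_id[0],
                            diagnosis_date = as.Date(character(0))))
    }
    df |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(diagnosis_date = min(.data$event_date), .groups = "drop")
  }
  if (criterion == "sensitive") {
    agg <- first_date_by_id(m)
  } else {
    inpt <- m[m$setting == "inpatient", , drop = FALSE]
    outpt <- m[m$setting == "outpatient", , drop = FALSE]
    if (distinct_dates) {
      outpt <- unique(outpt[, c("participant_id", "event_date")])
    }
    out_counts <- table(outpt$participant_id)
    qual_out <- names(out_counts)[out_counts >= 2]
    qual <- rbind(inpt[, c("participant_id", "event_date")],
                  outpt[as.character(outpt$participant_id) %in% qual_out,
                        c("participant_id", "event_date")])
    agg <- first_date_by_id(qual)
  }
  pos_ids <- agg$participant_id
  pos_dates <- agg$diagnosis_date

  idx <- match(participant_ids, pos_ids)
  status <- ifelse(is.na(idx), "negative", "positive")
  if (restricted) {
    ref_all <- as.Date(reference_dates)[match(participant_ids,
                                              names(reference_dates))]
    status[is.na(ref_all)] <- NA_character_
  }
  tibble::tibble(
    participant_id = participant_ids,
    status = status,
    diagnosis_date = pos_dates[idx]
  )
}
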