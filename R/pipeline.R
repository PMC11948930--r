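#' Reference date anchoring temporally restricted ascertainment
#'
#' For survey-positive participants the anchor is the survey date of first
#' self-report; for survey-negative participants it is the last completed
#' survey date (so negatives face a comparable look-back); participants
#' missing at every wave have no anchor (`NA`) and are excluded from the
#' restricted comparison.
#'
#' @param survey_cases output of [classify_survey_cohort()] for one
#'   condition.
#' @return A named `Date` vector (names = participant ids); `NA` for
#'   survey-missing participants.
#' @export
reference_date_for <- function(survey_cases) {
  ref <- dplyr::if_else(survey_cases$status == "positive",
                        survey_cases$diagnosis_date,
                        survey_cases$last_survey_date)
  ref[survey_cases$status == "missing"] <- as.Date(NA)
  stats::setNames(ref, survey_cases$participant_id)
}

#' Run the survey-vs-record concordance analysis end to end
#'
#' For every condition: classifies survey case status across waves
#' (carry-forward), ascertains record case status under the configured
#' criterion / temporality / source scope, and computes the agreement
#' statistics. Optionally also computes the behavior (smoking, alcohol)
#' agreement rows, Bland-Altman height/weight summaries, and agreement
#' stratified by utilization category.
#'
#' @param cohort a [generate_cohort()] result or a [read_cohort()] list
#'   (tables `participants`, `encounters`, `surveys`, and for behaviors /
#'   measurements `behaviors`, `vitals`).
#' @param code_sets named list of [condition_codeset()] objects; default
#'   the cohort's own code sets ([default_code_sets()] for synthetic
#'   cohorts).
#' @param criterion `"sensitive"` (any matching code) or `"specific"`
#'   (two outpatient dates or one inpatient).
#' @param temporality `"any"` (codes at any time) or `"prior"` (codes
#'   strictly before the per-participant reference date, personal-history
#'   codes excluded).
#' @param scope `"vha"` or `"combined"` (VHA + MDR).
#' @param window an [observation_window()].
#' @param exclude_codes optional named list: for a condition id, a
#'   character vector of code patterns; encounter codes matching any of
#'   them (prefix, after normalization) are not counted toward that
#'   condition (code-exclusion sensitivity analysis, e.g. dropping
#'   unspecified-depressive-disorder codes from a depression definition).
#' @param stratify_utilization also compute per-condition agreement within
#'   VHA utilization categories.
#' @param behaviors,measurements include the behavior agreement rows / the
#'   Bland-Altman height and per-wave weight summaries.
#' @param distinct_dates see [ascertain_specific()].
#' @return A `concordance_report`: list with `conditions` (one row per
#'   condition: prevalences, PA, NA, sensitivity, specificity, J),
#'   `behaviors`, `bland_altman`, `utilization` (stratified rows) and
#'   `manifest` (config echo and stage counts).
#' @export
run_concordance <- function(cohort,
                            code_sets = NULL,
                            criterion = c("sensitive", "specific"),
                            temporality = c("any", "prior"),
                            scope = c("vha", "combined"),
                            window = observation_window(),
                            exclude_codes = NULL,
                            stratify_utilization = FALSE,
                            behaviors = TRUE,
                            measurements = TRUE,
                            distinct_dates = TRUE) {
  criterion <- match.arg(criterion)
  temporality <- match.arg(temporality)
  scope <- match.arg(scope)
  for (tab in c("participants", "encounters", "surveys")) {
    if (is.null(cohort[[tab]])) {
      stop("cohort is missing the `", tab, "` table", call. = FALSE)
    }
  }
  if (is.null(code_sets)) {
    code_sets <- if (!is.null(cohort$code_sets)) cohort$code_sets
                 else default_code_sets()
  }
  ids <- cohort$participants$participant_id
  conds <- names(code_sets)

  if (!is.null(exclude_codes)) {
    for (cid in names(exclude_codes)) {
      cs <- code_sets[[cid]]
      if (is.null(cs)) next
      cs$exclude <- unique(c(cs$exclude, normalize_code(exclude_codes[[cid]])))
      code_sets[[cid]] <- cs
    }
  }

  util <- NULL
  if (stratify_utilization) {
    util <- classify_utilization_cohort(cohort$encounters, ids)
  }

  per_cond <- lapply(conds, function(cid) {
    sv <- classify_survey_cohort(cohort$surveys, cid)
    sv <- sv[match(ids, sv$participant_id), ]
    sv$participant_id <- ids  # participants with no survey rows: missing
    sv$status[is.na(sv$status)] <- "missing"

    ref <- if (temporality == "prior") reference_date_for(sv) else NULL
    eh <- ascertain_ehr_cohort(cohort$encounters, code_sets[[cid]], ids,
                               criterion = criterion, scope = scope,
                               window = window, reference_dates = ref,
                               distinct_dates = distinct_dates)
    survey_status <- ifelse(sv$status == "missing", NA_character_, sv$status)
    list(survey = survey_status, ehr = eh$status,
         n_survey_missing = sum(is.na(survey_status)),
         n_ehr_excluded = sum(is.na(eh$status)))
  })
  names(per_cond) <- conds

  cond_rows <- lapply(conds, function(cid) {
    pc <- per_cond[[cid]]
    t <- build_table(pc$survey, pc$ehr)
    dplyr::bind_cols(tibble::tibble(condition_id = cid), agreement_stats(t))
  })
  condition_report <- dplyr::bind_rows(cond_rows)

  strat_report <- NULL
  if (stratify_utilization) {
    strat_rows <- list()
    for (cat in c("irregular", "regular", "high-frequency")) {
      in_cat <- util$category == cat
      if (!any(in_cat)) next
      for (cid in conds) {
        pc <- per_cond[[cid]]
        s <- pc$survey[in_cat]; e <- pc$ehr[in_cat]
        if (!any(!is.na(s) & !is.na(e))) next
        t <- build_table(s, e)
        strat_rows[[length(strat_rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(utilization = cat, condition_id = cid),
          agreement_stats(t))
      }
    }
    strat_report <- dplyr::bind_rows(strat_rows)
  }

  behavior_report <- NULL
  if (behaviors && !is.null(cohort$behaviors)) {
    behavior_report <- behavior_agreement(cohort)
  }

  ba <- NULL
  if (measurements && !is.null(cohort$vitals)) {
    ba <- measurement_agreement(cohort)
  }

  manifest <- list(
    criterion = criterion, temporality = temporality, scope = scope,
    window = list(start = format(window$start), end = format(window$end)),
    n_participants = length(ids),
    n_encounters = nrow(cohort$encounters),
    n_survey_rows = nrow(cohort$surveys),
    conditions = conds,
    excluded_codes = exclude_codes,
    n_survey_missing = vapply(per_cond, `[[`, 0L, "n_survey_missing"),
    n_ehr_excluded = vapply(per_cond, `[[`, 0L, "n_ehr_excluded"))

  structure(
    list(conditions = condition_report, behaviors = behavior_report,
         bland_altman = ba, utilization = strat_report, manifest = manifest),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "concordance report: %d participants, criterion=%s, temporality=%s, scope=%s\n\n",
    m$n_participants, m$criterion, m$temporality, m$scope))
  print(format_condition_table(x$conditions))
  invisible(x)
}

#' Render a condition agreement table as aligned text
#'
#' @param conditions the `conditions` tibble of a [run_concordance()]
#'   report.
#' @return A data frame of formatted strings (printed tables show
#'   percentages at one decimal and J at two).
#' @export
format_condition_table <- function(conditions) {
  pct <- function(x) ifelse(is.na(x), "-", sprintf("%.1f%%", 100 * x))
  data.frame(
    condition = conditions$condition_id,
    `survey n (%)` = sprintf("%d (%.1f)", conditions$n_survey_pos,
                             100 * conditions$survey_prevalence),
    `record n (%)` = sprintf("%d (%.1f)", conditions$n_ehr_pos,
                             100 * conditions$ehr_prevalence),
    PA = pct(conditions$positive_agreement),
    NA. = pct(conditions$negative_agreement),
    J = ifelse(is.na(conditions$youden_j), "-",
               sprintf("%.2f", conditions$youden_j)),
    check.names = FALSE)
}

# Table-3 analogue: smoking and problem-drinking agreement
behavior_agreement <- function(cohort) {
  surveys <- cohort$surveys
  beh <- cohort$behaviors
  participants <- cohort$participants
  ids <- participants$participant_id
  sex <- participants$sex[match(ids, participants$participant_id)]

  surveys <- surveys[order(surveys$participant_id, surveys$wave), ]
  by_pid <- split(seq_len(nrow(surveys)), surveys$participant_id)
  beh$date <- as.Date(beh$date)
  audit <- beh[beh$kind == "auditc", ]
  smoke <- beh[beh$kind == "smoking", ]
  audit_by <- split(seq_len(nrow(audit)), audit$participant_id)
  smoke_by <- split(seq_len(nrow(smoke)), smoke$participant_id)

  phq_cols <- paste0("phq", 1:5)
  res <- lapply(seq_along(ids), function(k) {
    pid <- ids[k]
    rows <- by_pid[[pid]]
    if (is.null(rows)) {
      return(list(sv_drink = NA_character_, ehr_drink = NA_character_,
                  sv_smoke = NA_character_, ehr_smoke = NA_character_))
    }
    sdates <- as.Date(surveys$survey_date[rows])
    # survey problem drinking: any-wave endorsement of the 5-item screen
    flags <- vapply(rows, function(r) {
      items <- ifelse(is.na(unlist(surveys[r, phq_cols])), NA_character_,
                      ifelse(unlist(surveys[r, phq_cols]) == 1, "yes", "no"))
      phq_problem_drinking(items)
    }, "")
    sv_drink <- if (any(flags == "yes")) "yes"
                else if (any(flags == "no")) "no" else NA_character_
    # record alcohol misuse: AUDIT-C closest prior to the last survey
    arows <- audit_by[[pid]]
    ehr_drink <- NA_character_
    if (!is.null(arows)) {
      sc <- select_auditc(as.numeric(audit$value[arows]),
                          audit$date[arows], max(sdates))
      if (!is.na(sc)) ehr_drink <- auditc_misuse(sc, sex[k])
    }
    ans <- ifelse(is.na(surveys$smoke100[rows]), NA_character_,
                  ifelse(surveys$smoke100[rows] == 1, "yes", "no"))
    sv_smoke <- survey_ever_smoker(ans)
    if (sv_smoke == "missing") sv_smoke <- NA_character_
    srows <- smoke_by[[pid]]
    ehr_smoke <- NA_character_
    if (!is.null(srows)) {
      st <- select_ehr_smoking(smoke$value[srows], smoke$date[srows],
                               max(sdates))
      ehr_smoke <- if (st %in% c("current", "former")) "yes" else "no"
    }
    list(sv_drink = sv_drink, ehr_drink = ehr_drink,
         sv_smoke = sv_smoke, ehr_smoke = ehr_smoke)
  })
  to_status <- function(x) ifelse(is.na(x), NA_character_,
                                  ifelse(x == "yes", "positive", "negative"))
  g <- function(f) to_status(vapply(res, `[[`, "", f))
  rows <- list(
    smoking = build_table(g("sv_smoke"), g("ehr_smoke")),
    problem_drinking = build_table(g("sv_drink"), g("ehr_drink")))
  dplyr::bind_rows(lapply(names(rows), function(nm) {
    dplyr::bind_cols(tibble::tibble(behavior = nm), agreement_stats(rows[[nm]]))
  }))
}

# Bland-Altman analogue: one height summary plus per-wave weight summaries
measurement_agreement <- function(cohort) {
  surveys <- cohort$surveys
  vit <- cohort$vitals
  vit$date <- as.Date(vit$date)
  vit <- filter_extremes(vit)
  hts <- vit[vit$kind == "height", ]
  wts <- vit[vit$kind == "weight", ]
  hts_by <- split(seq_len(nrow(hts)), hts$participant_id)
  wts_by <- split(seq_len(nrow(wts)), wts$participant_id)
  surveys <- surveys[order(surveys$participant_id, surveys$wave), ]

  # height: one value per participant per source (mode / first recorded);
  # survey heights outside the plausibility bounds are dropped the same way
  sv_h <- surveys[!is.na(surveys$height_self) &
                    surveys$height_self >= 48 & surveys$height_self <= 95, ]
  sv_h_by <- split(seq_len(nrow(sv_h)), sv_h$participant_id)
  pids <- unique(surveys$participant_id)
  h_pairs <- vapply(pids, function(pid) {
    sr <- sv_h_by[[pid]]
    vr <- hts_by[[pid]]
    if (is.null(sr) || is.null(vr)) return(c(NA_real_, NA_real_))
    c(select_height(hts$value[vr], hts$date[vr]),
      select_height(sv_h$height_self[sr], as.Date(sv_h$survey_date[sr])))
  }, c(0, 0))
  height_ba <- tryCatch(bland_altman(h_pairs[1, ], h_pairs[2, ]),
                        error = function(e) NULL)

  # weight: pair each completed survey with the closest measurement
  # within a year, summarized by wave
  waves <- sort(unique(surveys$wave))
  weight_ba <- list()
  for (w in waves) {
    sw <- surveys[surveys$wave == w & !is.na(surveys$weight_self) &
                    surveys$weight_self >= 80 & surveys$weight_self <= 500, ]
    if (nrow(sw) == 0) next
    ehr_w <- vapply(seq_len(nrow(sw)), function(r) {
      vr <- wts_by[[sw$participant_id[r]]]
      if (is.null(vr)) return(NA_real_)
      select_weight(wts$value[vr], wts$date[vr], as.Date(sw$survey_date[r]))
    }, 0)
    ba <- tryCatch(bland_altman(ehr_w, sw$weight_self),
                   error = function(e) NULL)
    if (!is.null(ba)) weight_ba[[as.character(w)]] <- ba
  }
  list(height = height_ba, weight_by_wave = weight_ba)
}

#' Validate a printed concordance table against its own marginals
#'
#' For each row of a printed table (total N, survey and record positive
#' counts, positive agreement), reconstructs the candidate integer cell
#' counts and recomputes negative agreement and Youden's J, flagging rows
#' where no candidate reproduces the printed values at printed precision.
#'
#' @param printed data frame with columns `condition_id`, `n`, `n_survey`,
#'   `n_ehr`, `pa_percent`, `na_percent`, `j` (a file path to a delimited
#'   file with those columns is also accepted).
#' @return A tibble with one row per input row: the recomputed
#'   `na_percent` and `j` (from the first consistent candidate) and
#'   `consistent`; inconsistent rows are the discrepancy list.
#' @export
validate_printed_table <- function(printed) {
  if (is.character(printed)) {
    printed <- readr::read_csv(printed, show_col_types = FALSE,
                               progress = FALSE)
  }
  req <- c("condition_id", "n", "n_survey", "n_ehr", "pa_percent",
           "na_percent", "j")
  if (!all(req %in% names(printed))) {
    stop("printed table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(printed)), function(i) {
    r <- printed[i, ]
    chk <- check_printed_row(r$n, r$n_survey, r$n_ehr, r$pa_percent,
                             r$na_percent, r$j)
    ok <- which(chk$na_values == r$na_percent & chk$j_values == r$j)
    pick <- if (length(ok) > 0) ok[1] else 1L
    tibble::tibble(
      condition_id = r$condition_id,
      pa_percent = r$pa_percent,
      na_recomputed = chk$na_values[pick],
      j_recomputed = chk$j_values[pick],
      n_candidates = length(chk$candidates),
      consistent = chk$consistent)
  })
  dplyr::bind_rows(rows)
}
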