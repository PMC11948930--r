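#' Classify VHA health-care utilization frequency
#'
#' The observation period runs from a participant's first VHA encounter to
#' their last encounter on or before the cutoff. Categories:
#' \describe{
#'   \item{high-frequency}{more than 1 encounter per year in every year of
#'     the observation period}
#'   \item{regular}{at least 1 encounter per year on average}
#'   \item{irregular}{fewer than 1 per year on average but at least 1
#'     encounter}
#'   \item{none}{no encounters}
#' }
#' Years are consecutive 365.25-day intervals anchored at the first
#' encounter; the final partial interval is held to the more-than-one
#' standard only when it is at least half a year long. Observation time is
#' floored at 1 year so single-visit participants are classifiable (they
#' average 1/year: regular).
#'
#' @param dates encounter dates for one participant (any order; dates
#'   after the cutoff are dropped).
#' @param cutoff last eligible date (default 2020-09-18).
#' @return A `utilization_profile`: list with `first_date`, `last_date`,
#'   `observation_years`, `n_encounters`, `encounters_per_year` and
#'   `category`.
#' @export
classify_utilization <- function(dates, cutoff = as.Date("2020-09-18")) {
  dates <- as.Date(dates)
  dates <- sort(dates[!is.na(dates) & dates <= as.Date(cutoff)])
  if (length(dates) == 0) {
    return(structure(
      list(first_date = as.Date(NA), last_date = as.Date(NA),
           observation_years = NA_real_, n_encounters = 0L,
           encounters_per_year = 0, category = "none"),
      class = "utilization_profile"))
  }
  first <- dates[1]
  last <- dates[length(dates)]
  period_days <- as.numeric(last - first)
  obs_years <- max(period_days / 365.25, 1)
  n <- length(dates)
  avg <- n / obs_years

  # every-year test over 365.25-day intervals anchored at the first
  # encounter; vacuous when no interval qualifies for checking
  offsets <- as.numeric(dates - first)
  n_full <- floor(period_days / 365.25)
  remainder <- period_days - n_full * 365.25
  idx <- pmin(floor(offsets / 365.25), max(n_full, 0))
  counts <- tabulate(idx + 1, nbins = n_full + 1)
  checked <- seq_len(n_full)
  if (remainder >= 365.25 / 2) checked <- c(checked, n_full + 1)
  high <- length(checked) > 0 && all(counts[checked] >= 2)

  category <- if (high) "high-frequency"
              else if (avg >= 1) "regular"
              else "irregular"
  structure(
    list(first_date = first, last_date = last,
         observation_years = obs_years, n_encounters = n,
         encounters_per_year = avg, category = category),
    class = "utilization_profile")
}

#' @export
print.utilization_profile <- function(x, ...) {
  cat(sprintf("utilization: %s (%d encounters, %.2f/year over %.2f years)\n",
              x$category, x$n_encounters, x$encounters_per_year,
              ifelse(is.na(x$observation_years), 0, x$observation_years)))
  invisible(x)
}

#' Utilization categories for a whole cohort
#'
#' @param encounters encounter table (`participant_id`, `event_date`,
#'   `source`); only VHA rows are used.
#' @param participant_ids all cohort ids (participants without VHA
#'   encounters are category `"none"`).
#' @param cutoff last eligible date.
#' @return A tibble: `participant_id`, `category`,
#'   `encounters_per_year`, `n_encounters`.
#' @export
classify_utilization_cohort <- function(encounters, participant_ids,
                                        cutoff = as.Date("2020-09-18")) {
  enc <- encounters[encounters$source == "VHA", , drop = FALSE]
  split_dates <- split(as.Date(enc$event_date), enc$participant_id)
  profs <- lapply(split_dates, classify_utilization, cutoff = cutoff)
  got <- names(profs)
  idx <- match(as.character(participant_ids), got)
  pick <- function(fld, default) {
    vapply(idx, function(i) if (is.na(i)) default else profs[[i]][[fld]],
           default)
  }
  tibble::tibble(
    participant_id = participant_ids,
    category = pick("category", "none"),
    encounters_per_year = pick("encounters_per_year", 0),
    n_encounters = pick("n_encounters", 0L)
  )
}
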