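# builders for small in-code fixtures

enc_row <- function(id = "P1", setting = "outpatient", date = "2005-06-15",
                    code = "I10", system = "ICD10", source = "VHA",
                    position = 1L, personal_history = FALSE) {
  tibble::tibble(participant_id = id, source = source, setting = setting,
                 event_date = as.Date(date), code = code,
                 code_system = system, position = position,
                 personal_history = personal_history)
}

enc_table <- function(...) dplyr::bind_rows(...)

htn_codeset <- function(mode = "prefix") {
  condition_codeset("hypertension", "I10", "ICD10", mode)
}

# exhaustive per-record evaluator, independent of the package's
# aggregation path: walks records one by one
brute_sensitive <- function(records, codeset, window) {
  dates <- as.Date(character(0))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    d <- as.Date(r$event_date)
    if (d < window$start || d > window$end) next
    if (length(match_condition(r, codeset)) > 0) dates <- c(dates, d)
  }
  if (length(dates) == 0) list(status = "negative", date = as.Date(NA))
  else list(status = "positive", date = min(dates))
}

brute_specific <- function(records, codeset, window) {
  in_dates <- as.Date(character(0))
  out_dates <- as.Date(character(0))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    d <- as.Date(r$event_date)
    if (d < window$start || d > window$end) next
    if (length(match_condition(r, codeset)) == 0) next
    if (r$setting == "inpatient") in_dates <- c(in_dates, d)
    else out_dates <- c(out_dates, d)
  }
  qualifying <- in_dates
  if (length(unique(out_dates)) >= 2) qualifying <- c(qualifying, out_dates)
  if (length(qualifying) == 0) list(status = "negative", date = as.Date(NA))
  else list(status = "positive", date = min(qualifying))
}

random_records <- function(n, id = "P1",
                           window = observation_window()) {
  tibble::tibble(
    participant_id = id,
    source = sample(c("VHA", "MDR"), n, replace = TRUE),
    setting = sample(c("inpatient", "outpatient"), n, replace = TRUE,
                     prob = c(0.3, 0.7)),
    event_date = window$start +
      sample.int(as.numeric(window$end - window$start) + 400, n) - 200,
    code = sample(c("I10", "I109", "I11", "G43", "Z000"), n, replace = TRUE),
    code_system = "ICD10",
    position = sample.int(3, n, replace = TRUE),
    personal_history = sample(c(TRUE, FALSE), n, replace = TRUE,
                              prob = c(0.1, 0.9)))
}

random_table <- function() {
  two_by_two(a = sample(0:50, 1), b = sample(0:50, 1),
             c = sample(0:50, 1), d = sample(0:50, 1))
}

# small fast generator config for tests
test_config <- function(n = 500, seed = 1, ...) {
  sim_config(n_participants = n, encounter_rate = 0.3,
             wave_dates = as.Date(c("2003-07-01", "2008-07-01", "2013-07-01")),
             seed = seed, ...)
}
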