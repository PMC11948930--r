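#' Default synthetic condition parameters
#'
#' Three conditions spanning the prevalence and channel-accuracy ranges
#' seen in survey-vs-record concordance studies: a common chronic
#' condition, a common symptomatic condition, and a rare condition.
#' `code` is the generator's base diagnosis code for the condition (also
#' the prefix entry of [default_code_sets()]).
#'
#' @return A tibble with one row per condition: `condition_id`,
#'   `prevalence`, `survey_sens`, `survey_spec`, `ehr_sens`, `ehr_spec`,
#'   `mean_coded_encounters`, `code`, `code_system`.
#' @export
default_conditions <- function() {
  tibble::tibble(
    condition_id = c("hypertension", "migraine", "multiple_sclerosis"),
    prevalence = c(0.25, 0.18, 0.006),
    survey_sens = c(0.70, 0.60, 0.50),
    survey_spec = c(0.95, 0.93, 0.998),
    ehr_sens = c(0.80, 0.70, 0.60),
    ehr_spec = c(0.97, 0.96, 0.999),
    mean_coded_encounters = c(3, 2.5, 4),
    code = c("I10", "G43", "G35"),
    code_system = "ICD10"
  )
}

#' Code sets matching the default synthetic conditions
#'
#' @return A named list of [condition_codeset()] objects.
#' @export
default_code_sets <- function() {
  conds <- default_conditions()
  out <- lapply(seq_len(nrow(conds)), function(i) {
    condition_codeset(conds$condition_id[i], conds$code[i],
                      conds$code_system[i], "prefix")
  })
  stats::setNames(out, conds$condition_id)
}

#' Simulation configuration for a synthetic linked cohort
#'
#' Defines a cohort with latent per-condition true statuses observed
#' through two imperfect, conditionally independent channels: longitudinal
#' survey self-report (with wave nonresponse) and coded medical encounters
#' (with configurable coding sensitivity/specificity). A coupling
#' probability `shared_error_prob` optionally correlates the channels via
#' a common uniform draw; the default 0 gives conditional independence,
#' for which [expected_agreement()] is the exact closed-form oracle.
#'
#' @param n_participants cohort size (>= 1).
#' @param conditions tibble as [default_conditions()]; probabilities in
#'   \[0, 1\], `mean_coded_encounters` >= 1 (each record-positive
#'   participant receives at least one coded encounter).
#' @param wave_dates strictly increasing survey wave dates.
#' @param wave_response_prob probability a participant returns a given
#'   wave.
#' @param window an [observation_window()] bounding all encounter dates.
#' @param encounter_rate background (non-matching) encounters per
#'   person-year.
#' @param inpatient_fraction fraction of encounters that are inpatient.
#' @param mdr_fraction fraction of encounters recorded in MDR rather than
#'   VHA.
#' @param shared_error_prob channel-coupling probability in \[0, 1\].
#' @param height_mean,height_sd,weight_mean,weight_sd true-value
#'   distributions (inches, pounds).
#' @param height_report_bias,height_report_sd,weight_report_bias,weight_report_sd
#'   additive self-report bias and noise (self-report = truth + bias +
#'   noise; vitals measure truth with small device noise).
#' @param misuse_prevalence,smoking_prevalence latent behavior
#'   prevalences.
#' @param phq_sens,phq_spec,smoke_survey_sens,smoke_survey_spec,ehr_smoke_sens,ehr_smoke_spec
#'   behavior channel accuracies.
#' @param seed master seed; each output table draws from its own stream
#'   derived from it.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_participants = 1000,
                       conditions = default_conditions(),
                       wave_dates = as.Date(c("2001-07-01", "2004-07-01",
                                              "2007-07-01", "2011-07-01",
                                              "2014-07-01", "2016-07-01")),
                       wave_response_prob = 0.7,
                       window = observation_window(),
                       encounter_rate = 2,
                       inpatient_fraction = 0.1,
                       mdr_fraction = 0.3,
                       shared_error_prob = 0,
                       height_mean = 68, height_sd = 4,
                       weight_mean = 190, weight_sd = 35,
                       height_report_bias = 0.12, height_report_sd = 1,
                       weight_report_bias = -5.7, weight_report_sd = 11,
                       misuse_prevalence = 0.4, smoking_prevalence = 0.5,
                       phq_sens = 0.6, phq_spec = 0.9,
                       smoke_survey_sens = 0.95, smoke_survey_spec = 0.95,
                       ehr_smoke_sens = 0.9, ehr_smoke_spec = 0.8,
                       seed = 1L) {
  if (!is.numeric(n_participants) || n_participants < 1) {
    stop("invalid config: n_participants must be >= 1", call. = FALSE)
  }
  req <- c("condition_id", "prevalence", "survey_sens", "survey_spec",
           "ehr_sens", "ehr_spec", "mean_coded_encounters", "code",
           "code_system")
  if (!all(req %in% names(conditions)) || nrow(conditions) < 1) {
    stop("invalid config: conditions must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  probs <- unlist(conditions[c("prevalence", "survey_sens", "survey_spec",
                               "ehr_sens", "ehr_spec")])
  scalars <- c(wave_response_prob = wave_response_prob,
               inpatient_fraction = inpatient_fraction,
               mdr_fraction = mdr_fraction,
               shared_error_prob = shared_error_prob,
               misuse_prevalence = misuse_prevalence,
               smoking_prevalence = smoking_prevalence,
               phq_sens = phq_sens, phq_spec = phq_spec,
               smoke_survey_sens = smoke_survey_sens,
               smoke_survey_spec = smoke_survey_spec,
               ehr_smoke_sens = ehr_smoke_sens,
               ehr_smoke_spec = ehr_smoke_spec)
  if (any(probs < 0 | probs > 1)) {
    stop("invalid config: condition probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  bad <- names(scalars)[scalars < 0 | scalars > 1]
  if (length(bad) > 0) {
    stop("invalid config: probability out of [0, 1]: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(conditions$mean_coded_encounters < 1)) {
    stop("invalid config: mean_coded_encounters must be >= 1", call. = FALSE)
  }
  wave_dates <- as.Date(wave_dates)
  if (length(wave_dates) < 1 || is.unsorted(wave_dates, strictly = TRUE)) {
    stop("invalid config: wave_dates must be strictly increasing",
         call. = FALSE)
  }
  stopifnot(inherits(window, "observation_window"))
  if (encounter_rate < 0) {
    stop("invalid config: encounter_rate must be nonnegative", call. = FALSE)
  }
  structure(
    list(n_participants = as.integer(n_participants), conditions = conditions,
         wave_dates = wave_dates, wave_response_prob = wave_response_prob,
         window = window, encounter_rate = encounter_rate,
         inpatient_fraction = inpatient_fraction,
         mdr_fraction = mdr_fraction,
         shared_error_prob = shared_error_prob,
         height_mean = height_mean, height_sd = height_sd,
         weight_mean = weight_mean, weight_sd = weight_sd,
         height_report_bias = height_report_bias,
         height_report_sd = height_report_sd,
         weight_report_bias = weight_report_bias,
         weight_report_sd = weight_report_sd,
         misuse_prevalence = misuse_prevalence,
         smoking_prevalence = smoking_prevalence,
         phq_sens = phq_sens, phq_spec = phq_spec,
         smoke_survey_sens = smoke_survey_sens,
         smoke_survey_spec = smoke_survey_spec,
         ehr_smoke_sens = ehr_smoke_sens, ehr_smoke_spec = ehr_smoke_spec,
         seed = as.integer(seed)),
    class = "sim_config")
}

# one reproducible stream per output table, derived from the master seed
# so adding a table does not perturb the others
stream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131 + k * 7919) %% 2147483647)
}

random_dates <- function(n, start, end) {
  start + floor(stats::runif(n) * (as.numeric(end - start) + 1))
}

#' Generate a synthetic linked survey + EHR cohort
#'
#' Draws latent true condition statuses, passes them through the survey
#' and record channels, and materializes the five linked tables consumed
#' by the ascertainment pipeline. Deterministic given the config seed.
#'
#' Channel model, per participant and condition: true status `T ~
#' Bernoulli(prevalence)`; the survey channel self-reports with
#' probability `survey_sens` when `T = 1` and `1 - survey_spec` when
#' `T = 0`; the record channel codes the condition with probability
#' `ehr_sens` / `1 - ehr_spec`. Record-positive participants receive at
#' least one matching coded encounter (count `1 + Poisson(mean - 1)`) on
#' uniform dates in the window; everyone receives background encounters at
#' `encounter_rate` per person-year carrying a non-matching filler code.
#' Survey-positive participants answer "yes" from a uniformly chosen
#' responded wave onward and "no" before; nonresponded waves are absent
#' rows.
#'
#' @param config a [sim_config()].
#' @return A `synthetic_cohort`: list with tibbles `participants`,
#'   `encounters`, `surveys`, `vitals`, `behaviors`, plus `latent`
#'   (per-participant channel flags, the ground truth for validation) and
#'   the echoed `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_participants
  conds <- config$conditions
  win <- config$window
  ids <- sprintf("P%06d", seq_len(n))
  window_years <- as.numeric(win$end - win$start) / 365.25

  # --- latent truth and channel flags (stream 1) ---
  set.seed(stream_seed(config$seed, 1))
  sex <- ifelse(stats::runif(n) < 0.28, "female", "male")
  true_height <- stats::rnorm(n, config$height_mean, config$height_sd)
  true_weight <- stats::rnorm(n, config$weight_mean, config$weight_sd)
  misuse_true <- stats::runif(n) < config$misuse_prevalence
  smoker_true <- stats::runif(n) < config$smoking_prevalence

  latent <- tibble::tibble(participant_id = ids)
  participants <- tibble::tibble(
    participant_id = ids, sex = sex,
    true_height = true_height, true_weight = true_weight,
    misuse_true = misuse_true, smoker_true = smoker_true)
  for (i in seq_len(nrow(conds))) {
    cid <- conds$condition_id[i]
    truth <- stats::runif(n) < conds$prevalence[i]
    p_s <- ifelse(truth, conds$survey_sens[i], 1 - conds$survey_spec[i])
    p_e <- ifelse(truth, conds$ehr_sens[i], 1 - conds$ehr_spec[i])
    # coupled participants evaluate both channels on one uniform draw
    # (marginals preserved; default coupling probability is 0)
    coupled <- stats::runif(n) < config$shared_error_prob
    u_shared <- stats::runif(n)
    u_s <- ifelse(coupled, u_shared, stats::runif(n))
    u_e <- ifelse(coupled, u_shared, stats::runif(n))
    s_flag <- u_s < p_s
    e_flag <- u_e < p_e
    participants[[paste0("true_", cid)]] <- truth
    latent[[paste0("survey_", cid)]] <- s_flag
    latent[[paste0("ehr_", cid)]] <- e_flag
  }

  # --- encounters (stream 2) ---
  set.seed(stream_seed(config$seed, 2))
  n_bg <- stats::rpois(n, config$encounter_rate * window_years)
  bg <- tibble::tibble(
    participant_id = rep(ids, n_bg),
    code = "Z000", code_system = "ICD10")
  coded <- list()
  for (i in seq_len(nrow(conds))) {
    cid <- conds$condition_id[i]
    e_flag <- latent[[paste0("ehr_", cid)]]
    n_codes <- integer(n)
    n_codes[e_flag] <- 1 + stats::rpois(sum(e_flag),
                                        conds$mean_coded_encounters[i] - 1)
    coded[[i]] <- tibble::tibble(
      participant_id = rep(ids, n_codes),
      code = conds$code[i], code_system = conds$code_system[i])
  }
  enc <- dplyr::bind_rows(bg, coded)
  m <- nrow(enc)
  enc$event_date <- random_dates(m, win$start, win$end)
  enc$source <- ifelse(stats::runif(m) < config$mdr_fraction, "MDR", "VHA")
  enc$setting <- ifelse(stats::runif(m) < config$inpatient_fraction,
                        "inpatient", "outpatient")
  enc$position <- sample.int(3L, m, replace = TRUE)
  enc$personal_history <- FALSE
  encounters <- enc[order(enc$participant_id, enc$event_date),
                    c("participant_id", "source", "setting", "event_date",
                      "code", "code_system", "position", "personal_history")]

  # --- surveys (stream 3) ---
  set.seed(stream_seed(config$seed, 3))
  n_waves <- length(config$wave_dates)
  responded <- matrix(stats::runif(n * n_waves) < config$wave_response_prob,
                      n, n_waves)
  # guarantee types even when a participant answers no wave (row omitted)
  resp_idx <- which(responded, arr.ind = TRUE)
  resp_idx <- resp_idx[order(resp_idx[, 1], resp_idx[, 2]), , drop = FALSE]
  surveys <- tibble::tibble(
    participant_id = ids[resp_idx[, 1]],
    wave = as.integer(resp_idx[, 2]),
    survey_date = config$wave_dates[resp_idx[, 2]])
  n_resp_waves <- tabulate(resp_idx[, 1], nbins = n)
  for (i in seq_len(nrow(conds))) {
    cid <- conds$condition_id[i]
    s_flag <- latent[[paste0("survey_", cid)]]
    # uniformly chosen responded wave of first self-report
    first_rank <- ifelse(n_resp_waves > 0,
                         1 + floor(stats::runif(n) * n_resp_waves), NA)
    rank_in_pid <- stats::ave(seq_len(nrow(surveys)),
                              surveys$participant_id, FUN = seq_along)
    pid_i <- match(surveys$participant_id, ids)
    ans <- ifelse(s_flag[pid_i] & rank_in_pid >= first_rank[pid_i], 1L, 0L)
    surveys[[cid]] <- ans
  }
  # behavior survey items
  pid_i <- match(surveys$participant_id, ids)
  phq_flag <- ifelse(misuse_true, stats::runif(n) < config$phq_sens,
                     stats::runif(n) < 1 - config$phq_spec)
  smoke_flag <- ifelse(smoker_true,
                       stats::runif(n) < config$smoke_survey_sens,
                       stats::runif(n) < 1 - config$smoke_survey_spec)
  n_rows <- nrow(surveys)
  endorse <- matrix(0L, n_rows, 5)
  pos_rows <- which(phq_flag[pid_i])
  if (length(pos_rows) > 0) {
    # at least one of the five items endorsed, others independently
    forced <- sample.int(5L, length(pos_rows), replace = TRUE)
    endorse[cbind(pos_rows, forced)] <- 1L
    extra <- matrix(stats::runif(length(pos_rows) * 5) < 0.25,
                    length(pos_rows), 5)
    endorse[pos_rows, ] <- pmax(endorse[pos_rows, , drop = FALSE], extra * 1L)
  }
  for (j in 1:5) surveys[[paste0("phq", j)]] <- endorse[, j]
  surveys$smoke100 <- as.integer(smoke_flag[pid_i])
  surveys$height_self <- round(
    true_height[pid_i] + config$height_report_bias +
      stats::rnorm(n_rows, 0, config$height_report_sd), 1)
  surveys$weight_self <- round(
    true_weight[pid_i] + config$weight_report_bias +
      stats::rnorm(n_rows, 0, config$weight_report_sd), 1)

  # --- vitals (stream 4) ---
  set.seed(stream_seed(config$seed, 4))
  n_h <- 1 + stats::rpois(n, 1)
  heights <- tibble::tibble(
    participant_id = rep(ids, n_h), kind = "height",
    value = round(true_height[rep(seq_len(n), n_h)] +
                    stats::rnorm(sum(n_h), 0, 0.3)))
  heights$date <- random_dates(nrow(heights), win$start, win$end)
  # weights measured near each wave so a within-1-year pair usually exists
  wgrid <- expand.grid(p = seq_len(n), w = seq_len(n_waves))
  has_w <- stats::runif(nrow(wgrid)) < 0.8
  wgrid <- wgrid[has_w, ]
  weights <- tibble::tibble(
    participant_id = ids[wgrid$p], kind = "weight",
    value = round(true_weight[wgrid$p] + stats::rnorm(nrow(wgrid), 0, 4), 1),
    date = config$wave_dates[wgrid$w] +
      floor(stats::runif(nrow(wgrid), -300, 301)))
  weights$date <- pmin(pmax(weights$date, win$start), win$end)
  vitals <- dplyr::bind_rows(heights, weights)[
    , c("participant_id", "date", "kind", "value")]
  vitals <- vitals[order(vitals$participant_id, vitals$date), ]

  # --- behaviors (stream 5) ---
  set.seed(stream_seed(config$seed, 5))
  n_audit <- stats::rpois(n, 2)
  ai <- rep(seq_len(n), n_audit)
  audit <- tibble::tibble(
    participant_id = ids[ai], kind = "auditc",
    value = as.character(ifelse(misuse_true[ai],
                                pmin(12, 3 + stats::rpois(length(ai), 2.5)),
                                stats::rbinom(length(ai), 12, 0.12))))
  audit$date <- random_dates(nrow(audit), win$start, win$end)
  n_smk <- stats::rpois(n, 2)
  si <- rep(seq_len(n), n_smk)
  smk_pos <- ifelse(smoker_true[si],
                    stats::runif(length(si)) < config$ehr_smoke_sens,
                    stats::runif(length(si)) < 1 - config$ehr_smoke_spec)
  smoke <- tibble::tibble(
    participant_id = ids[si], kind = "smoking",
    value = ifelse(smk_pos,
                   ifelse(stats::runif(length(si)) < 0.5, "current", "former"),
                   "never"))
  smoke$date <- random_dates(nrow(smoke), win$start, win$end)
  behaviors <- dplyr::bind_rows(audit, smoke)[
    , c("participant_id", "date", "kind", "value")]
  behaviors <- behaviors[order(behaviors$participant_id, behaviors$date), ]

  code_sets <- stats::setNames(
    lapply(seq_len(nrow(conds)), function(i) {
      condition_codeset(conds$condition_id[i], conds$code[i],
                        conds$code_system[i], "prefix")
    }), conds$condition_id)

  structure(
    list(participants = participants, encounters = encounters,
         surveys = surveys, vitals = vitals, behaviors = behaviors,
         latent = latent, code_sets = code_sets, config = config),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic linked cohort: %d participants, %d conditions\n  %d encounters, %d survey rows, %d vitals, %d behavior records\n",
    nrow(x$participants), nrow(x$config$conditions), nrow(x$encounters),
    nrow(x$surveys), nrow(x$vitals), nrow(x$behaviors)))
  invisible(x)
}

#' Closed-form expected agreement for a simulated condition
#'
#' Under the generator's channel model, the expected 2x2 cell
#' probabilities are, conditional on true status, `P(S = 1, E = 1 | T) =
#' rho * min(pS, pE) + (1 - rho) * pS * pE` (common-uniform coupling with
#' probability `rho = shared_error_prob`; the default `rho = 0` gives the
#' conditionally independent product), mixed over `P(T = 1) = prevalence`.
#' With `rho = 0` and prevalence `p`: `P(both+) = p * s1 * s2 +
#' (1 - p)(1 - c1)(1 - c2)`, etc. The agreement statistics are the exact
#' values of the formulas applied to those probabilities — the oracle
#' against which pipeline estimates are validated.
#'
#' @param config a [sim_config()].
#' @param condition_id one of the configured conditions.
#' @return A one-row tibble: cell probabilities `p11`, `p10`, `p01`,
#'   `p00`, prevalences, `positive_agreement`, `negative_agreement`,
#'   `sensitivity`, `specificity`, `youden_j`.
#' @export
expected_agreement <- function(config, condition_id) {
  stopifnot(inherits(config, "sim_config"))
  conds <- config$conditions
  i <- match(condition_id, conds$condition_id)
  if (is.na(i)) stop("unknown condition id: ", condition_id, call. = FALSE)
  rho <- config$shared_error_prob
  cell11 <- function(ps, pe) rho * pmin(ps, pe) + (1 - rho) * ps * pe
  p <- conds$prevalence[i]
  joint <- function(truth) {
    ps <- if (truth) conds$survey_sens[i] else 1 - conds$survey_spec[i]
    pe <- if (truth) conds$ehr_sens[i] else 1 - conds$ehr_spec[i]
    p11 <- cell11(ps, pe)
    c(p11 = p11, p10 = ps - p11, p01 = pe - p11, p00 = 1 - ps - pe + p11)
  }
  cells <- p * joint(TRUE) + (1 - p) * joint(FALSE)
  p11 <- cells["p11"]; p10 <- cells["p10"]
  p01 <- cells["p01"]; p00 <- cells["p00"]
  sens <- p11 / (p11 + p01)
  spec <- p00 / (p10 + p00)
  tibble::tibble(
    condition_id = condition_id,
    p11 = unname(p11), p10 = unname(p10),
    p01 = unname(p01), p00 = unname(p00),
    survey_prevalence = unname(p11 + p10),
    ehr_prevalence = unname(p11 + p01),
    positive_agreement = unname(2 * p11 / (2 * p11 + p10 + p01)),
    negative_agreement = unname(2 * p00 / (2 * p00 + p10 + p01)),
    sensitivity = unname(sens),
    specificity = unname(spec),
    youden_j = unname(sens + spec - 1))
}

#' Write a synthetic cohort's tables to a directory
#'
#' Emits the five delimited tables (UTF-8, header row, ISO-8601 dates)
#' in the schemas the reader functions expect, the condition code sets,
#' and the generator configuration as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(dir, paste0(name, ".csv")), progress = FALSE)
  }
  w(cohort$participants, "participants")
  w(cohort$encounters, "encounters")
  w(cohort$surveys, "surveys")
  w(cohort$vitals, "vitals")
  w(cohort$behaviors, "behaviors")
  conds <- cohort$config$conditions
  w(tibble::tibble(condition_id = conds$condition_id,
                   code_system = conds$code_system,
                   code = conds$code, match_mode = "prefix"),
    "code_sets")
  cfg <- cohort$config
  cfg$window <- list(start = format(cfg$window$start),
                     end = format(cfg$window$end))
  cfg$wave_dates <- format(cfg$wave_dates)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing the five tables.
#' @return A list of tibbles: `participants`, `encounters`, `surveys`,
#'   `vitals`, `behaviors`, and `code_sets` (as [condition_codeset()]
#'   objects) when present.
#' @export
read_cohort <- function(dir) {
  rd <- function(name) {
    readr::read_csv(file.path(dir, paste0(name, ".csv")),
                    show_col_types = FALSE, progress = FALSE)
  }
  out <- list(participants = rd("participants"), encounters = rd("encounters"),
              surveys = rd("surveys"), vitals = rd("vitals"),
              behaviors = rd("behaviors"))
  cs <- file.path(dir, "code_sets.csv")
  if (file.exists(cs)) out$code_sets <- read_code_sets(cs)
  out
}
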