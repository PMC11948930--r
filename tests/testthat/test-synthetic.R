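test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(n_participants = 0), "n_participants")
  expect_error(sim_config(wave_response_prob = 1.2), "wave_response_prob")
  expect_error(sim_config(encounter_rate = -1), "encounter_rate")
  expect_error(sim_config(wave_dates = as.Date(c("2004-01-01", "2001-01-01"))),
               "wave_dates")
  bad <- default_conditions()
  bad$prevalence[1] <- 1.5
  expect_error(sim_config(conditions = bad), "probabilities")
  bad <- default_conditions()
  bad$mean_coded_encounters[1] <- 0.5
  expect_error(sim_config(conditions = bad), "mean_coded_encounters")
})

test_that("the generator is deterministic given the seed", {
  c1 <- generate_cohort(test_config(n = 200, seed = 9))
  c2 <- generate_cohort(test_config(n = 200, seed = 9))
  for (tab in c("participants", "encounters", "surveys", "vitals",
                "behaviors", "latent")) {
    expect_identical(c1[[tab]], c2[[tab]])
  }
  c3 <- generate_cohort(test_config(n = 200, seed = 10))
  expect_false(identical(c1$encounters, c3$encounters))
})

test_that("cohort tables respect the window and participant roster", {
  coh <- generate_cohort(test_config(n = 300, seed = 5))
  win <- coh$config$window
  expect_true(all(coh$encounters$event_date >= win$start &
                    coh$encounters$event_date <= win$end))
  ids <- coh$participants$participant_id
  for (tab in c("encounters", "surveys", "vitals", "behaviors")) {
    expect_true(all(coh[[tab]]$participant_id %in% ids))
  }
  # wave indices unique per participant
  expect_false(any(duplicated(coh$surveys[c("participant_id", "wave")])))
})

test_that("record-positive participants always carry a matching coded encounter", {
  coh <- generate_cohort(test_config(n = 400, seed = 6))
  cs <- default_code_sets()
  for (cid in names(cs)) {
    e_flag <- coh$latent[[paste0("ehr_", cid)]]
    matched <- match_codes(coh$encounters$code, coh$encounters$code_system,
                           cs[[cid]])
    with_code <- unique(coh$encounters$participant_id[matched])
    expect_setequal(coh$participants$participant_id[e_flag], with_code)
  }
})

test_that("expected_agreement reproduces hand-evaluated closed forms", {
  conds <- tibble::tibble(
    condition_id = c("perfect", "coinflip", "partial"),
    prevalence = c(0.5, 0.3, 0.2),
    survey_sens = c(1, 0.4, 0.8),
    survey_spec = c(1, 0.6, 1),
    ehr_sens = c(1, 0.7, 0.6),
    ehr_spec = c(1, 0.9, 1),
    mean_coded_encounters = 2, code = c("A01", "B02", "C03"),
    code_system = "ICD10")
  cfg <- sim_config(n_participants = 10, conditions = conds)

  e <- expected_agreement(cfg, "perfect")
  expect_equal(e$positive_agreement, 1)
  expect_equal(e$negative_agreement, 1)
  expect_equal(e$youden_j, 1)

  # survey channel independent of truth (sens = 1 - spec): J = 0
  e <- expected_agreement(cfg, "coinflip")
  expect_equal(e$youden_j, 0, tolerance = 1e-12)

  # p=0.2, s1=0.8, s2=0.6, perfect specificity: PA = 0.192/0.280
  e <- expected_agreement(cfg, "partial")
  expect_equal(e$p11, 0.2 * 0.8 * 0.6)
  expect_equal(e$positive_agreement, 0.192 / 0.280, tolerance = 1e-12)

  expect_error(expected_agreement(cfg, "nonesuch"), "unknown condition")
})

test_that("expected cell probabilities always sum to one", {
  set.seed(51)
  for (i in 1:50) {
    conds <- tibble::tibble(
      condition_id = "x", prevalence = runif(1),
      survey_sens = runif(1), survey_spec = runif(1),
      ehr_sens = runif(1), ehr_spec = runif(1),
      mean_coded_encounters = 2, code = "X01", code_system = "ICD10")
    cfg <- sim_config(n_participants = 10, conditions = conds,
                      shared_error_prob = runif(1))
    e <- expected_agreement(cfg, "x")
    expect_equal(e$p11 + e$p10 + e$p01 + e$p00, 1, tolerance = 1e-12)
    expect_true(all(c(e$p11, e$p10, e$p01, e$p00) >= -1e-12))
  }
})

test_that("expected J is nondecreasing in record coding sensitivity", {
  grid <- seq(0.05, 1, by = 0.05)
  set.seed(52)
  for (i in 1:10) {
    base <- tibble::tibble(
      condition_id = "x", prevalence = runif(1, 0.05, 0.5),
      survey_sens = runif(1, 0.5, 1), survey_spec = runif(1, 0.8, 1),
      ehr_sens = NA_real_, ehr_spec = runif(1, 0.8, 1),
      mean_coded_encounters = 2, code = "X01", code_system = "ICD10")
    j <- vapply(grid, function(s) {
      conds <- base; conds$ehr_sens <- s
      expected_agreement(sim_config(n_participants = 10, conditions = conds),
                         "x")$youden_j
    }, 0)
    expect_true(all(diff(j) >= -1e-12))
  }
})

test_that("empirical dual-positive rate matches the closed form at scale", {
  conds <- tibble::tibble(
    condition_id = "target", prevalence = 0.2,
    survey_sens = 0.8, survey_spec = 1,
    ehr_sens = 0.6, ehr_spec = 1,
    mean_coded_encounters = 2, code = "T01", code_system = "ICD10")
  cfg <- sim_config(n_participants = 200000, conditions = conds,
                    encounter_rate = 0.05,
                    wave_dates = as.Date(c("2004-07-01", "2010-07-01")),
                    seed = 53)
  coh <- generate_cohort(cfg)
  dual <- mean(coh$latent$survey_target & coh$latent$ehr_target)
  p <- 0.2 * 0.8 * 0.6
  se <- sqrt(p * (1 - p) / 200000)
  expect_lt(abs(dual - p), 3 * se)
  expect_equal(expected_agreement(cfg, "target")$p11, p)
})

test_that("written cohorts round-trip through the readers", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(test_config(n = 60, seed = 8))
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$encounters), nrow(coh$encounters))
  expect_equal(as.Date(back$encounters$event_date), coh$encounters$event_date)
  expect_equal(back$surveys$hypertension, coh$surveys$hypertension)
  expect_equal(names(back$code_sets), sort(coh$config$conditions$condition_id))
  expect_true(file.exists(file.path(dir, "config.json")))
})
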