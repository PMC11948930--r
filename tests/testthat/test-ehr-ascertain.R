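test_that("code normalization strips decimals and case, and is idempotent", {
  expect_equal(normalize_code("250.00"), "25000")
  expect_equal(normalize_code("f32.9"), "F329")
  expect_equal(normalize_code(" V70.0 "), "V700")
  expect_error(normalize_code(""), "non-empty")
  expect_error(normalize_code("   "), "non-empty")
  set.seed(7)
  raw <- replicate(50, paste(sample(c(LETTERS, 0:9, ".", " "), 6,
                                    replace = TRUE), collapse = ""))
  raw <- raw[nzchar(trimws(raw)) & trimws(raw) != "."]
  expect_equal(normalize_code(normalize_code(raw)), normalize_code(raw))
})

test_that("matching honors any diagnostic position and prefix/exact modes", {
  rec <- enc_row(code = "I10", position = 3L)
  expect_equal(match_condition(rec, htn_codeset()), "I10")
  expect_length(match_condition(enc_row(code = "J45"), htn_codeset()), 0)
  # prefix vs exact on a child code
  child <- enc_row(code = "I109")
  expect_equal(match_condition(child, htn_codeset("prefix")), "I109")
  expect_length(match_condition(child, htn_codeset("exact")), 0)
  # same digits under a different code system do not match
  expect_false(match_codes("I10", "ICD9", htn_codeset()))
})

test_that("sensitive criterion: any single in-window matching code is a case", {
  one <- enc_row(date = "2005-06-15")
  cs <- ascertain_sensitive(one, htn_codeset())
  expect_equal(cs$status, "positive")
  expect_equal(cs$diagnosis_date, as.Date("2005-06-15"))

  late <- enc_row(date = "2020-09-19")  # day after window end
  expect_equal(ascertain_sensitive(late, htn_codeset())$status, "negative")
  expect_equal(ascertain_sensitive(
    enc_row(date = "2020-09-18"), htn_codeset())$status, "positive")

  two <- enc_table(enc_row(date = "2010-01-05"), enc_row(date = "2003-02-01"))
  expect_equal(ascertain_sensitive(two, htn_codeset())$diagnosis_date,
               as.Date("2003-02-01"))
})

test_that("specific criterion: one inpatient or two distinct outpatient dates", {
  one_out <- enc_row(setting = "outpatient")
  expect_equal(ascertain_sensitive(one_out, htn_codeset())$status, "positive")
  expect_equal(ascertain_specific(one_out, htn_codeset())$status, "negative")

  one_in <- enc_row(setting = "inpatient", date = "2007-03-03")
  cs <- ascertain_specific(one_in, htn_codeset())
  expect_equal(cs$status, "positive")
  expect_equal(cs$diagnosis_date, as.Date("2007-03-03"))

  same_day <- enc_table(enc_row(date = "2006-05-05", position = 1L),
                        enc_row(date = "2006-05-05", position = 2L))
  expect_equal(ascertain_specific(same_day, htn_codeset())$status, "negative")
  expect_equal(ascertain_specific(same_day, htn_codeset(),
                                  distinct_dates = FALSE)$status, "positive")

  two_days <- enc_table(enc_row(date = "2006-05-05"),
                        enc_row(date = "2006-08-09"))
  cs <- ascertain_specific(two_days, htn_codeset())
  expect_equal(cs$status, "positive")
  expect_equal(cs$diagnosis_date, as.Date("2006-05-05"))
})

test_that("temporal restriction is strict and excludes personal-history codes", {
  ref <- as.Date("2006-05-05")
  on_ref <- enc_row(date = "2006-05-05")
  expect_equal(restrict_prior(on_ref, htn_codeset(),
                              reference_date = ref)$status, "negative")
  before <- enc_row(date = "2006-05-04")
  expect_equal(restrict_prior(before, htn_codeset(),
                              reference_date = ref)$status, "positive")
  ph <- enc_row(date = "2004-01-01", personal_history = TRUE)
  expect_equal(restrict_prior(ph, htn_codeset(),
                              reference_date = ref)$status, "negative")
  expect_error(restrict_prior(before, htn_codeset(),
                              reference_date = as.Date(NA)), "reference date")

  # reference at/after window end = unrestricted minus personal-history codes
  set.seed(11)
  for (i in 1:20) {
    recs <- random_records(sample(1:15, 1))
    no_ph <- recs[!recs$personal_history, ]
    r1 <- restrict_prior(recs, htn_codeset(),
                         reference_date = observation_window()$end + 1)
    r2 <- ascertain_sensitive(no_ph, htn_codeset())
    expect_equal(r1$status, r2$status)
    expect_equal(r1$diagnosis_date, r2$diagnosis_date)
  }
})

test_that("merging sources takes the union and the earliest diagnosis date", {
  pos1 <- ascertain_sensitive(enc_row(date = "2005-01-01"), htn_codeset())
  pos2 <- ascertain_sensitive(enc_row(date = "2003-06-01"), htn_codeset())
  neg <- ascertain_sensitive(enc_row(code = "J45"), htn_codeset())

  expect_equal(merge_sources(pos1, pos2)$diagnosis_date, as.Date("2003-06-01"))
  expect_equal(merge_sources(pos2, pos1)$diagnosis_date, as.Date("2003-06-01"))
  expect_equal(merge_sources(neg, neg)$status, "negative")
  m <- merge_sources(pos1, neg)
  expect_equal(m$status, "positive")
  expect_equal(m$diagnosis_date, as.Date("2005-01-01"))

  other <- ascertain_sensitive(enc_row(code = "G43"),
                               condition_codeset("migraine", "G43"))
  expect_error(merge_sources(pos1, other), "different conditions")
})

test_that("both criteria agree with an exhaustive per-record evaluator", {
  set.seed(12)
  win <- observation_window()
  for (i in 1:60) {
    recs <- random_records(sample(1:20, 1))
    b_sen <- brute_sensitive(recs, htn_codeset(), win)
    b_spe <- brute_specific(recs, htn_codeset(), win)
    a_sen <- ascertain_sensitive(recs, htn_codeset(), win)
    a_spe <- ascertain_specific(recs, htn_codeset(), win)
    expect_equal(a_sen$status, b_sen$status)
    expect_equal(a_spe$status, b_spe$status)
    if (a_sen$status == "positive") {
      expect_equal(a_sen$diagnosis_date, b_sen$date)
    }
    if (a_spe$status == "positive") {
      expect_equal(a_spe$diagnosis_date, b_spe$date)
    }
    # specific implies sensitive
    if (a_spe$status == "positive") expect_equal(a_sen$status, "positive")
  }
})

test_that("shrinking the window never turns a negative into a positive", {
  set.seed(13)
  for (i in 1:30) {
    recs <- random_records(sample(1:15, 1))
    full <- observation_window()
    mid <- observation_window(full$start + 2000, full$end - 2000)
    for (f in list(ascertain_sensitive, ascertain_specific)) {
      if (f(recs, htn_codeset(), full)$status == "negative") {
        expect_equal(f(recs, htn_codeset(), mid)$status, "negative")
      }
    }
  }
})

test_that("cohort-scale ascertainment matches per-participant ascertainment", {
  set.seed(14)
  ids <- sprintf("P%02d", 1:25)
  recs <- dplyr::bind_rows(lapply(ids[1:20], function(id) {
    random_records(sample(1:8, 1), id = id)
  }))
  for (crit in c("sensitive", "specific")) {
    for (sc in c("vha", "combined")) {
      got <- ascertain_ehr_cohort(recs, htn_codeset(), ids,
                                  criterion = crit, scope = sc)
      for (k in seq_along(ids)) {
        sub <- recs[recs$participant_id == ids[k], ]
        if (sc == "vha") sub <- sub[sub$source == "VHA", ]
        want <- if (crit == "sensitive") ascertain_sensitive(sub, htn_codeset())
                else ascertain_specific(sub, htn_codeset())
        expect_equal(got$status[k], want$status)
        expect_equal(got$diagnosis_date[k], want$diagnosis_date)
      }
    }
  }
})
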