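test_that("agreement statistics match hand-evaluated values on (3,1,1,5)", {
  t <- two_by_two(3, 1, 1, 5)
  expect_equal(positive_agreement(t), 6 / 8)
  expect_equal(negative_agreement(t), 10 / 12)
  expect_equal(youden_j(t), 3 / 4 + 5 / 6 - 1)
  st <- agreement_stats(t)
  expect_equal(st$sensitivity, 3 / 4)
  expect_equal(st$specificity, 5 / 6)
  expect_equal(st$youden_j, st$sensitivity + st$specificity - 1)
})

test_that("boundary tables give 0, 1 or an absent statistic, never a coerced 0", {
  expect_equal(positive_agreement(two_by_two(7, 0, 0, 0)), 1)
  expect_equal(positive_agreement(two_by_two(0, 2, 3, 5)), 0)
  expect_equal(negative_agreement(two_by_two(0, 0, 0, 9)), 1)
  expect_equal(negative_agreement(two_by_two(2, 1, 1, 0)), 0)
  # no positives anywhere: PA undefined
  expect_true(is.na(positive_agreement(two_by_two(0, 0, 0, 10))))
  # empty record margin: J undefined
  expect_true(is.na(youden_j(two_by_two(0, 3, 0, 7))))
  expect_true(is.na(youden_j(two_by_two(3, 0, 7, 0))))
  # perfect and independence tables
  expect_equal(youden_j(two_by_two(4, 0, 0, 6)), 1)
  expect_equal(youden_j(two_by_two(5, 5, 5, 5)), 0)
})

test_that("printed-formula forms equal the direct cell forms on random tables", {
  set.seed(101)
  for (i in 1:500) {
    t <- random_table()
    if (2 * t$a + t$b + t$c > 0) {
      expect_equal(positive_agreement(t), 2 * t$a / (2 * t$a + t$b + t$c))
    }
    if (2 * t$d + t$b + t$c > 0) {
      expect_equal(negative_agreement(t), 2 * t$d / (2 * t$d + t$b + t$c))
    }
  }
})

test_that("J is prevalence-invariant and PA/NA are symmetric in the two sources", {
  set.seed(102)
  for (i in 1:100) {
    t <- random_table()
    if ((t$a + t$c) == 0 || (t$b + t$d) == 0) next
    k <- sample(1:5, 1); m <- sample(1:5, 1)
    scaled <- two_by_two(k * t$a, m * t$b, k * t$c, m * t$d)
    if ((scaled$a + scaled$c) > 0 && (scaled$b + scaled$d) > 0) {
      expect_equal(youden_j(scaled), youden_j(t))
    }
    swapped <- two_by_two(t$a, t$c, t$b, t$d)
    expect_equal(positive_agreement(swapped), positive_agreement(t))
    expect_equal(negative_agreement(swapped), negative_agreement(t))
  }
})

test_that("build_table counts pairs and drops missing statuses", {
  t <- build_table(c("positive", "positive", "negative", "negative"),
                   c("positive", "negative", "positive", "negative"))
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 1, 1, 1))

  sv <- c(rep("positive", 4), rep("negative", 6), NA, "positive")
  eh <- c(rep("positive", 3), "negative", "positive",
          rep("negative", 5), "positive", NA)
  t <- build_table(sv, eh)
  expect_equal(c(t$a, t$b, t$c, t$d), c(3, 1, 1, 5))
  expect_equal(t$n, 10)
  expect_equal(t$n_dropped, 2)

  expect_error(build_table(c(NA, "positive"), c("positive", NA)), "missing")
  expect_error(build_table("yes", "positive"), "values other than")
})

test_that("round_half_up rounds halves away from zero at printed precision", {
  expect_equal(round_half_up(31.45, 1), 31.5)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-31.45, 1), -31.5)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(31.4499, 1), 31.4)
})

test_that("reconstruct_cells inverts printed positive agreement", {
  # unique candidate case: 430/1363 rounds to 31.5, 428/1363 to 31.4
  cand <- reconstruct_cells(116288, 887, 476, 31.5)
  expect_length(cand, 1)
  expect_equal(cand[[1]]$a, 215)
  expect_equal(cand[[1]]$b, 887 - 215)
  expect_equal(cand[[1]]$c, 476 - 215)
  expect_equal(cand[[1]]$d, 116288 - 887 - 476 + 215)

  cand <- reconstruct_cells(10, 5, 5, 100.0)
  expect_length(cand, 1)
  expect_equal(c(cand[[1]]$a, cand[[1]]$b, cand[[1]]$c, cand[[1]]$d),
               c(5, 0, 0, 5))

  cand <- reconstruct_cells(20, 4, 6, 0.0)
  expect_equal(cand[[1]]$a, 0)

  expect_error(reconstruct_cells(100, 10, 10, 99.9), "no integer")
  expect_error(reconstruct_cells(5, 10, 2, 50), "margins exceed")
})

test_that("reconstruct_cells round-trip recovers the true dual-positive count", {
  set.seed(103)
  for (i in 1:100) {
    t <- random_table()
    if (t$a + t$b + t$c == 0) next
    pa_printed <- round_half_up(100 * positive_agreement(t), 1)
    cand <- reconstruct_cells(t$n, t$a + t$b, t$a + t$c, pa_printed)
    expect_true(t$a %in% vapply(cand, `[[`, 0L, "a"))
  }
})

test_that("reconstruct_statistics picks the rounding-interval midpoint candidate", {
  st <- reconstruct_statistics(116288, 887, 476, 31.5)
  expect_equal(st$a, 215)
  expect_equal(st$n_candidates, 1)
  expect_equal(st$negative_agreement_percent, 99.6)
  expect_equal(st$youden_j, 0.45)
})
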