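test_that("recall averaging is the unweighted day mean", {
  rec <- data.frame(person_id = c(1, 1, 2, 3, 3),
                    day_index = c(1, 2, 1, 1, 2),
                    grains = c(2.0, 0.0, 3.5, 1, 3),
                    fruit  = c(0, 4, 1, 0, 4),
                    veg    = c(2, 0, 2, 2, 0))
  out <- average_recalls(rec)
  expect_equal(unname(out$amounts["1", ]), c(1.0, 2.0, 1.0))
  expect_equal(unname(out$amounts["2", ]), c(3.5, 1, 2))   # single day kept
  expect_equal(unname(out$amounts["3", ]), c(2, 2, 1))
  expect_equal(nrow(out$excluded), 0)
})

test_that("persons with no complete recall are excluded with a reason", {
  rec <- data.frame(person_id = c(1, 2), day_index = c(1, 1),
                    grains = c(NA, 2), fruit = c(1, 3))
  out <- average_recalls(rec)
  expect_equal(out$ids, "2")
  expect_equal(out$excluded$id, 1)
  expect_match(out$excluded$reason, "no complete recall")
})

test_that("tertile cutpoints follow the inverse-ECDF convention", {
  amounts <- cbind(a = c(0, 1:9), b = rep(0, 10), c = c(0, rep(5, 9)))
  w <- capture_warnings(rule <- fit_categorization(amounts))
  expect_length(w, 2)   # one per degenerate column
  expect_match(w, "distinct positive", all = TRUE)
  expect_equal(rule$t1[1], 3)
  expect_equal(rule$t2[1], 6)
  expect_false(rule$degenerate[1])
  expect_true(rule$degenerate[2])   # all-zero column
  expect_true(rule$degenerate[3])   # zero spread
})

test_that("categorization boundary behavior: ties go to the lower level", {
  rule <- data.frame(food = "a", t1 = 3, t2 = 6, degenerate = FALSE)
  class(rule) <- c("categorization_rule", "data.frame")
  amounts <- matrix(c(0, 0.5, 3, 3.1, 6, 6.5), ncol = 1)
  lev <- categorize(amounts, rule)
  expect_equal(as.vector(lev), c(1L, 2L, 2L, 3L, 3L, 4L))
  # enumeration oracle on the same grid
  for (i in seq_along(amounts))
    expect_equal(lev[i], oracle_level(amounts[i], 3, 6))
  expect_error(categorize(matrix(-1, 1, 1), rule), "negative amount")
})

test_that("degenerate columns collapse positives to the consumed level", {
  amounts <- matrix(c(0, 5, 5, 0, 5), ncol = 1, dimnames = list(NULL, "a"))
  rule <- suppressWarnings(fit_categorization(amounts))
  lev <- categorize(amounts, rule)
  expect_equal(as.vector(lev), c(1L, 2L, 2L, 1L, 2L))
})

test_that("categorization is monotone and consumer tertiles are balanced", {
  set.seed(402)
  for (rep in 1:25) {
    x <- c(rep(0, sample(0:20, 1)), stats::rlnorm(sample(30:200, 1)))
    x <- sample(x)
    rule <- fit_categorization(matrix(x, ncol = 1))
    lev <- as.vector(categorize(matrix(x, ncol = 1), rule))
    # monotone: sorting amounts sorts levels
    expect_true(all(diff(lev[order(x)]) >= 0))
    # each consumed tertile within 1 person of n_pos/3 (continuous, no ties)
    npos <- sum(x > 0)
    expect_true(all(abs(tabulate(lev[lev > 1] - 1L, 3L) - npos / 3) <= 1))
  }
})

test_that("eligibility filters apply in documented order with a tally", {
  tab <- data.frame(
    id = 1:10, sex = "Female", age = c(25, 30, 40, 50, 60, 35, 45, 22, 70, 33),
    race = "NHWhite",
    income_ratio = c(1.0, 1.31, 2.0, 0.5, 1.30, 0.9, 1.5, 1.2, 0.7, 1.1),
    pregnant = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                 FALSE),
    n_recalls = 1L)
  out <- apply_eligibility(tab, eligibility_criteria())
  expect_equal(length(out$ids), 5)
  expect_equal(unname(out$tally[["income"]]), 3)
  expect_equal(unname(out$tally[["pregnancy"]]), 2)
  expect_equal(names(out$tally),
               c("sex", "age", "race_ethnicity", "income", "pregnancy",
                 "diet_completeness"))
  # idempotent: re-applying removes nobody
  again <- apply_eligibility(out$kept, eligibility_criteria())
  expect_equal(again$ids, out$ids)
  expect_true(all(again$tally == 0))
})

test_that("eligibility boundaries are inclusive where the study says so", {
  tab <- data.frame(id = 1:4, sex = "Female", age = c(20, 80, 19, 81),
                    race = "Mexican", income_ratio = 1.30, pregnant = FALSE,
                    n_recalls = 1L)
  out <- apply_eligibility(tab, eligibility_criteria())
  expect_equal(out$ids, 1:2)   # ages 20 and 80 retained, PIR 1.30 retained
  expect_error(apply_eligibility(tab[, -3], eligibility_criteria()),
               "missing required column")
})

test_that("risk-flag thresholds reproduce the stated boundary behavior", {
  tab <- data.frame(
    total_chol = c(200, 201, 150, NA),
    ldl = c(100, 100, 151, NA),
    chol_meds = c(FALSE, FALSE, FALSE, TRUE),
    bmi = c(30, 29.9, 35, NA),
    sbp = c(140, 141, 120, NA), dbp = c(90, 91, 80, NA),
    bp_meds = c(FALSE, FALSE, FALSE, NA),
    glucose = c(126, 127, NA, NA), diabetes_meds = c(FALSE, FALSE, TRUE, NA),
    smoker = c(TRUE, FALSE, NA, NA))
  fl <- derive_risk_flags(tab)
  expect_equal(fl$high_cholesterol, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(fl$obesity, c(TRUE, FALSE, TRUE, NA))       # BMI 30 inclusive
  expect_equal(fl$hypertension, c(FALSE, TRUE, FALSE, NA))  # strict >
  expect_equal(fl$diabetes, c(FALSE, TRUE, TRUE, NA))       # meds OR glucose
  expect_equal(fl$current_smoker, c(TRUE, FALSE, NA, NA))
})

test_that("categorization rules round-trip through disk", {
  amounts <- matrix(stats::rlnorm(300), 100, 3,
                    dimnames = list(NULL, c("a", "b", "c")))
  rule <- fit_categorization(amounts)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rule(rule, path)
  back <- read_rule(path)
  expect_equal(back$t1, rule$t1)
  expect_equal(back$t2, rule$t2)
  expect_equal(back$degenerate, rule$degenerate)
})
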