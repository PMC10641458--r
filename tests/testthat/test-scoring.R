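# Brute-force oracle for three-valued criterion scoring: enumerate every
# completion of the missing entries; the outcome is determinate only if
# all completions agree on "any item == 3".
oracle_any3 <- function(items) {
  slots <- lapply(items, function(v) if (is.na(v)) 0:3 else v)
  outcomes <- apply(do.call(expand.grid, slots), 1, function(r) any(r == 3))
  if (all(outcomes)) TRUE else if (!any(outcomes)) FALSE else NA
}

test_that("average daily gaming time follows the 5:2 weekly aggregation", {
  expect_equal(average_daily_time(0, 0), 0)
  expect_equal(average_daily_time(70, 70), 70)
  expect_equal(average_daily_time(60, 120), (5 * 60 + 2 * 120) / 7)
  expect_true(is.na(average_daily_time(NA, 30)))
  expect_error(average_daily_time(-1, 10), "nonnegative")
})

test_that("excessive-time threshold is the type-7 90th percentile", {
  expect_equal(excessive_time_threshold(rep(40, 20))$minutes, 40)
  thr <- excessive_time_threshold(1:100)
  expect_equal(thr$minutes, 90.1)
  expect_equal(thr$rule, "type7_linear_interpolation")
  expect_error(excessive_time_threshold(c(1:5, NA, NA)), "115")
})

test_that("criterion scoring matches exhaustive enumeration over {0..3, NA}^2", {
  vals <- c(0:3, NA)
  for (a in vals) for (b in vals) {
    expect_tv_equal(score_igd_criterion(a, b), oracle_any3(list(a, b)))
  }
  # spot values quoted for the instrument's rule
  expect_true(score_igd_criterion(3, 0))
  expect_false(score_igd_criterion(2, 2))
  expect_true(score_igd_criterion(NA, 3))
  expect_tv_equal(score_igd_criterion(NA, 1), NA)
})

test_that("adverse-consequences criterion matches enumeration over four items", {
  # all 4^4 complete combinations
  g <- expand.grid(a = 0:3, b = 0:3, c = 0:3, d = 0:3)
  got <- score_hg_c4(g$a, g$b, g$c, g$d)
  expect_identical(got, apply(g, 1, function(r) any(r == 3)))
  # missing-data cases against the completion oracle
  set.seed(42)
  for (i in 1:50) {
    v <- sample(c(0:3, NA), 4, replace = TRUE)
    expect_tv_equal(score_hg_c4(v[1], v[2], v[3], v[4]), oracle_any3(as.list(v)))
  }
  expect_tv_equal(score_hg_c4(0, 0, NA, 0), NA)
})

test_that("excessive time-and-frequency criterion is a three-valued conjunction", {
  expect_true(score_hg_c1(c(6, 0, 0, 0), 120, 115))
  expect_true(score_hg_c1(c(6, 0, 0, 0), 115, 115))  # inclusive threshold
  expect_false(score_hg_c1(c(5, 5, 5, 5), 300, 115))
  expect_false(score_hg_c1(c(6, 6, 6, 6), 114.9, 115))
  expect_tv_equal(score_hg_c1(c(6, 0, 0, 0), NA, 115), NA)
  expect_false(score_hg_c1(c(5, 4, 3, 2), NA, 115))
  expect_tv_equal(score_hg_c1(c(NA, 0, 0, 0), 120, 115), NA)
  expect_false(score_hg_c1(c(NA, 0, 0, 0), 10, 115))
  expect_error(score_hg_c1(c(7, 0, 0, 0), 10, 115), "0..6")
})

test_that("IGD classification thresholds and indeterminacy rule", {
  expect_equal(as.character(classify_igd(c(rep(TRUE, 5), rep(FALSE, 4)))$igd_class),
               "full")
  expect_equal(as.character(classify_igd(c(rep(TRUE, 2), rep(FALSE, 7)))$igd_class),
               "subclinical")
  expect_equal(as.character(classify_igd(rep(FALSE, 9))$igd_class), "none")
  # 4 true + 1 unknown straddles the full/subclinical boundary
  expect_equal(as.character(classify_igd(c(rep(TRUE, 4), NA, rep(FALSE, 4)))$igd_class),
               "indeterminate")
  # 1 true + 1 unknown straddles none/subclinical
  expect_equal(as.character(classify_igd(c(TRUE, NA, rep(FALSE, 7)))$igd_class),
               "indeterminate")
  # 2 true + 2 unknown stays subclinical under every completion
  expect_equal(as.character(classify_igd(c(TRUE, TRUE, NA, NA, rep(FALSE, 5)))$igd_class),
               "subclinical")
})

test_that("classification is permutation invariant and determinate on complete data", {
  set.seed(7)
  for (i in 1:200) {
    crit <- sample(c(TRUE, FALSE, NA), 9, replace = TRUE,
                   prob = c(0.3, 0.5, 0.2))
    c1 <- classify_igd(crit)$igd_class
    c2 <- classify_igd(sample(crit))$igd_class
    expect_identical(as.character(c1), as.character(c2))
    if (!anyNA(crit)) expect_false(as.character(c1) == "indeterminate")
  }
})

test_that("HG flag is the three-valued OR of the assessable criteria", {
  tv <- c(TRUE, FALSE, NA)
  for (a in tv) for (b in tv) for (c in tv) {
    expect_tv_equal(classify_hg(a, b, c), a | b | c)
  }
  expect_true(classify_hg(FALSE, TRUE, FALSE))
  expect_false(classify_hg(FALSE, FALSE, FALSE))
  expect_tv_equal(classify_hg(FALSE, NA, FALSE), NA)
})

test_that("raising a response or gaming time never revokes endorsement", {
  set.seed(11)
  for (i in 1:100) {
    v <- sample(0:3, 4, replace = TRUE)
    before <- score_hg_c4(v[1], v[2], v[3], v[4])
    j <- sample(4, 1)
    if (v[j] < 3) {
      v[j] <- v[j] + sample.int(3 - v[j], 1)
      after <- score_hg_c4(v[1], v[2], v[3], v[4])
      expect_true(after >= before)
    }
  }
  f <- c(6, 0, 0, 0)
  t1 <- seq(0, 300, by = 25)
  flags <- score_hg_c1(matrix(f, 13, 4, byrow = TRUE), t1, 115)
  expect_true(all(diff(flags) >= 0))
})

test_that("score_cohort reproduces the hand-scored six-subject fixture", {
  sc <- score_cohort(validate_responses(hand_cohort()))
  expect_equal(as.character(sc$records$igd_class),
               c("none", "full", "subclinical", "none", "indeterminate", "none"))
  expect_tv_equal(sc$records$hg_flag, c(FALSE, FALSE, TRUE, TRUE, FALSE, NA))
  expect_equal(sc$records$igd_criteria_met[1:4], c(0, 5, 2, 0))
  expect_equal(sc$summary$hg_determinate_n, 5)
  expect_equal(sc$summary$igd_determinate_n, 5)
  expect_equal(sc$records$avg_daily_minutes[4], 120)
})

test_that("an all-zero cohort scores fully determinate and negative", {
  sc <- score_cohort(validate_responses(blank_table(50)))
  expect_equal(sum(sc$records$hg_flag), 0)
  expect_equal(as.character(unique(sc$records$igd_class)), "none")
  expect_equal(sc$summary$hg_determinate_n, 50)
  expect_equal(sc$summary$igd_determinate_n, 50)
})

test_that("cohort HG share stays in the binomial band around the implied rate", {
  cfg <- synthetic_config(n_subjects = 5000)
  truth <- implied_hg_rate(cfg, n = 50000, seed = 2)
  sc <- score_cohort(generate_cohort(cfg, seed = 97))
  hg <- sc$records$hg_flag
  n_det <- sum(!is.na(hg))
  band <- qbinom(c(0.005, 0.995), n_det, truth)
  expect_gte(sum(hg, na.rm = TRUE), band[1])
  expect_lte(sum(hg, na.rm = TRUE), band[2])
})

test_that("extension items feed criterion 3 into the OR when supplied", {
  df <- blank_table(3)
  df$ext1 <- c(0L, 3L, 0L)
  df$ext2 <- 0L
  df$ext3 <- 0L
  df$ext4 <- c(0L, 0L, NA_integer_)
  tab <- df[, !(names(df) %in% c("ext1", "ext2", "ext3", "ext4"))]
  tab <- cbind(validate_responses(tab), df[c("ext1", "ext2", "ext3", "ext4")])
  sc <- score_cohort(tab, extension_items = c("ext1", "ext2", "ext3", "ext4"))
  expect_tv_equal(sc$records$hg_c3_risky_context, c(FALSE, TRUE, NA))
  expect_tv_equal(sc$records$hg_flag, c(FALSE, TRUE, NA))
})
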