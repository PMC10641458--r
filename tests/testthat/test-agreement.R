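test_that("Wald prevalence intervals match hand arithmetic", {
  e0 <- prevalence_ci(0, 100)
  expect_equal(e0$proportion, 0)
  expect_equal(c(e0$ci_low, e0$ci_high), c(0, 0))
  e <- prevalence_ci(50, 100)
  z <- qnorm(0.975)
  expect_equal(e$ci_low, 0.5 - z * sqrt(0.25 / 100))
  expect_equal(e$ci_high, 0.5 + z * sqrt(0.25 / 100))
  # the published HG share pattern: 90 of 866 -> 10.4% (8.4-12.4)
  ehg <- prevalence_ci(90, 866)
  expect_equal(round_half_up(100 * ehg$proportion, 1), 10.4)
  expect_lt(abs(ehg$ci_low - 0.084), 0.001)
  expect_lt(abs(ehg$ci_high - 0.124), 0.001)
  expect_error(prevalence_ci(5, 0), "positive")
  expect_error(prevalence_ci(11, 10), "count")
  # interval width shrinks as 1/sqrt(n)
  widths <- vapply(c(100, 400, 1600), function(n)
    with(prevalence_ci(round(0.3 * n), n), ci_high - ci_low), numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.02)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.02)
  # wilson stays inside [0,1] even at the boundary
  w <- prevalence_ci(0, 20, method = "wilson")
  expect_gte(w$ci_low, 0)
  expect_gt(w$ci_high, 0)
})

test_that("crosstab excludes indeterminate subjects and keeps count", {
  a <- rep(c(TRUE, FALSE), 5)
  ct <- crosstab(a, a)
  expect_equal(ct$table[1, 1] + ct$table[2, 2], 10)
  expect_equal(ct$table[1, 2] + ct$table[2, 1], 0)
  b <- a
  b[4] <- NA
  ct2 <- crosstab(a, b)
  expect_equal(ct2$n_used, 9)
  expect_equal(ct2$n_excluded, 1)
  # hand-counted 12-subject fixture
  x <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, NA, FALSE, TRUE)
  y <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, NA, TRUE, TRUE, FALSE, FALSE)
  ct3 <- crosstab(x, y)
  expect_equal(unname(ct3$table), rbind(c(3, 2), c(1, 4)))
  expect_equal(ct3$n_excluded, 2)
  expect_error(crosstab(1:3 > 1, 1:4 > 1), "equal length")
})

test_that("Cohen's kappa matches hand arithmetic and its identities", {
  expect_equal(cohens_kappa(rbind(c(10, 0), c(0, 10)))$kappa, 1)
  k <- cohens_kappa(rbind(c(20, 5), c(10, 65)))
  expect_equal(k$po, 0.85)
  expect_equal(k$pe, 0.60)
  expect_equal(k$kappa, 0.625)
  expect_equal(k$interpretation, "substantial")
  # independence table (outer product of margins) gives exactly zero
  tab0 <- outer(c(60, 40), c(70, 30)) / 100
  expect_equal(cohens_kappa(tab0)$kappa, 0)
  # symmetry under transposition
  tab <- rbind(c(7, 3), c(12, 44))
  expect_equal(cohens_kappa(tab)$kappa, cohens_kappa(t(tab))$kappa)
  # degenerate margin: kappa reported, test flagged unavailable
  kd <- cohens_kappa(rbind(c(0, 0), c(5, 15)))
  expect_false(kd$test_available)
  expect_true(is.na(kd$p_value))
})

test_that("kappa agrees with the e1071 cross-check on random tables", {
  skip_if_not_installed("e1071")
  set.seed(8)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    expect_equal(cohens_kappa(tab)$kappa,
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  }
})

test_that("kappa z-test holds its nominal size under independence", {
  set.seed(123)
  reps <- 2000
  rej <- 0
  for (i in 1:reps) {
    a <- runif(500) < 0.3
    b <- runif(500) < 0.4
    k <- cohens_kappa(crosstab(a, b)$table)
    if (k$test_available && k$p_value < 0.05) rej <- rej + 1
  }
  expect_gte(rej / reps, 0.03)
  expect_lte(rej / reps, 0.07)
})

test_that("overlap summary reports the published share structure", {
  # fixture: 88 HG-positive with determinate IGD, of whom 31 meet
  # neither IGD class -> HG-only share 35.2%
  n <- 400
  hg <- rep(FALSE, n)
  hg[1:88] <- TRUE
  cls <- rep("none", n)
  cls[1:40] <- "subclinical"   # 40 of the HG are subclinical
  cls[41:57] <- "full"         # 17 full
  # 31 HG have neither (88 - 40 - 17 = 31); add non-HG IGD cases
  cls[101:106] <- "full"       # 6 IGD without HG -> 17/23 = 73.9%
  cls[107:150] <- "subclinical"
  rec <- data.frame(hg_flag = hg,
                    igd_class = factor(cls, levels = c("none", "subclinical",
                                                       "full", "indeterminate")))
  ov <- overlap_summary(rec)
  expect_equal(ov$n_both_determinate, n)
  expect_equal(round_half_up(100 * ov$shares$hg_only$proportion, 1), 35.2)
  expect_equal(ov$shares$igd_meeting_hg$count, 17)
  expect_equal(ov$shares$igd_meeting_hg$n_valid, 23)
  expect_equal(ov$shares$subclinical_meeting_hg$count, 40)
  expect_equal(sum(ov$cells), n)
  # every-IGD-is-HG cohort gives a 100% share
  rec2 <- data.frame(hg_flag = c(TRUE, TRUE, FALSE, FALSE),
                     igd_class = factor(c("full", "full", "none", "none"),
                                        levels = levels(rec$igd_class)))
  expect_equal(overlap_summary(rec2)$shares$igd_meeting_hg$proportion, 1)
})

test_that("overlap summary equals brute-force set algebra on a scored cohort", {
  sc <- score_cohort(generate_cohort(synthetic_config(n_subjects = 1500),
                                     seed = 44))
  rec <- sc$records
  ov <- overlap_summary(rec)
  keep <- !is.na(rec$hg_flag) & rec$igd_class != "indeterminate"
  hg <- rec$hg_flag[keep]
  cls <- as.character(rec$igd_class[keep])
  expect_equal(ov$n_both_determinate, sum(keep))
  expect_equal(unname(ov$cells["TRUE", "none"]), sum(hg & cls == "none"))
  expect_equal(unname(ov$cells["FALSE", "subclinical"]),
               sum(!hg & cls == "subclinical"))
  expect_equal(ov$shares$hg_only$proportion,
               sum(hg & cls == "none") / sum(hg))
  expect_equal(ov$kappa$hg_vs_any_igd$table[1, 1],
               sum(hg & cls %in% c("subclinical", "full")))
  # conservation: cells always sum to the determinate count
  expect_equal(sum(ov$cells), ov$n_both_determinate)
})

test_that("subgroup prevalence recovers constructed group rates", {
  rec <- data.frame(
    hg_flag = c(rep(TRUE, 8), rep(FALSE, 32), rep(TRUE, 3), rep(FALSE, 57)),
    gender = c(rep("male", 40), rep("female", 60))
  )
  sp <- subgroup_prevalence(rec, "hg_flag", "gender")
  expect_equal(sp$proportion[sp$group == "male"], 0.2)
  expect_equal(sp$proportion[sp$group == "female"], 0.05)
  expect_equal(sp$n_valid, c(40, 60))
  # single-level grouping reproduces the cohort estimate
  rec$all <- "everyone"
  sp1 <- subgroup_prevalence(rec, "hg_flag", "all")
  whole <- prevalence_ci(11, 100)
  expect_equal(sp1$proportion, whole$proportion)
  expect_equal(sp1$ci_low, whole$ci_low)
  # indeterminate-only subgroup yields a flagged empty estimate
  rec2 <- data.frame(hg_flag = c(TRUE, NA), gender = c("a", "b"))
  sp2 <- subgroup_prevalence(rec2, "hg_flag", "gender")
  expect_equal(sp2$n_valid[sp2$group == "b"], 0)
  expect_true(is.na(sp2$proportion[sp2$group == "b"]))
  expect_error(subgroup_prevalence(rec, "hg_flag", "nope"), "not found")
})
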