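L2 <- cbind(c(rep(0.7, 5), rep(0, 6)), c(rep(0, 5), rep(0.6, 6)))
Phi2 <- matrix(c(1, 0.3, 0.3, 1), 2)

test_that("parallel analysis retains nothing from flat eigenvalues", {
  pa <- parallel_analysis(rep(1, 8), n = 300, p = 8, reps = 150,
                          quantile = 0.95, seed = 1)
  expect_equal(pa$suggested_k, 0L)
  expect_error(parallel_analysis(rep(1, 8), 300, 8, reps = 50, seed = 1),
               ">= 100")
})

test_that("parallel analysis finds two factors in two-factor data", {
  ks <- vapply(1:10, function(s) {
    X <- factor_data(1000, L2, Phi2, seed = 40 + s)
    ev <- eigen(cor(X), only.values = TRUE)$values
    parallel_analysis(ev, n = 1000, p = 11, reps = 200,
                      seed = s)$suggested_k
  }, integer(1))
  expect_gte(sum(ks == 2), 9)
})

test_that("parallel analysis stays at zero on pure noise", {
  ks <- vapply(1:10, function(s) {
    set.seed(600 + s)
    X <- matrix(rnorm(500 * 11), 500, 11)
    ev <- eigen(cor(X), only.values = TRUE)$values
    parallel_analysis(ev, n = 500, p = 11, reps = 200, seed = s)$suggested_k
  }, integer(1))
  expect_gte(sum(ks == 0), 9)
})

test_that("parallel analysis is seed-reproducible", {
  ev <- eigen(cor(factor_data(500, L2, Phi2, seed = 3)),
              only.values = TRUE)$values
  a <- parallel_analysis(ev, 500, 11, reps = 150, seed = 10)
  b <- parallel_analysis(ev, 500, 11, reps = 150, seed = 10)
  expect_identical(a$reference, b$reference)
})

test_that("empirical Kaiser criterion evaluates its reference formula", {
  ev <- eigen(ref_R <- csas_reference_correlations()$r,
              only.values = TRUE)$values
  ekc <- empirical_kaiser_criterion(ev, n = 693, p = 11)
  # direct formula evaluation as an in-test oracle
  a <- (1 + sqrt(11 / 693))^2
  ref <- numeric(11)
  for (j in 1:11) ref[j] <- max((11 - sum(ev[seq_len(j - 1)])) /
                                  (11 - j + 1) * a, 1)
  expect_equal(ekc$reference, ref)
  # flat unit spectrum retains nothing
  expect_equal(empirical_kaiser_criterion(rep(1, 11), 693, 11)$suggested_k, 0L)
  expect_error(empirical_kaiser_criterion(c(1, 2, 3), 100, 3), "descending")
})

test_that("EKC collapses to the Kaiser rule as n grows", {
  ev <- eigen(csas_reference_correlations()$r, only.values = TRUE)$values
  ekc <- empirical_kaiser_criterion(ev, n = 1e12, p = 11)
  expect_lt(abs(ekc$reference[1] - 1), 1e-5)
  expect_true(all(ekc$reference[-1] >= 1))
  serial_kaiser <- which.min(c(ev > 1, FALSE)) - 1
  expect_equal(ekc$suggested_k, as.integer(serial_kaiser))
})

test_that("EKC finds two factors in two-factor data", {
  ks <- vapply(1:10, function(s) {
    X <- factor_data(1000, L2, Phi2, seed = 40 + s)
    ev <- eigen(cor(X), only.values = TRUE)$values
    empirical_kaiser_criterion(ev, n = 1000, p = 11)$suggested_k
  }, integer(1))
  expect_gte(sum(ks == 2), 9)
})

test_that("comparison data recovers the generating factor count", {
  # 20 fixed seeds per condition; the retention criterion's documented
  # accuracy is "at least 90% of seeds at the generating k"
  k2 <- vapply(1:20, function(s) {
    X <- factor_data(1000, L2, Phi2, seed = 100 + s)
    comparison_data(data = X, max_k = 4, reps = 100, seed = s)$suggested_k
  }, integer(1))
  expect_gte(sum(k2 == 2), 18)
  k1 <- vapply(1:20, function(s) {
    X <- factor_data(1000, matrix(0.7, 10, 1), diag(1), seed = 200 + s)
    comparison_data(data = X, max_k = 4, reps = 100, seed = s)$suggested_k
  }, integer(1))
  expect_gte(sum(k1 == 1), 18)
})

test_that("comparison data stays at the noise boundary on pure noise", {
  kn <- vapply(1:10, function(s) {
    set.seed(300 + s)
    X <- matrix(rnorm(500 * 11), 500, 11)
    comparison_data(data = X, max_k = 4, reps = 100, seed = s)$suggested_k
  }, integer(1))
  expect_true(all(kn <= 1))
  expect_gte(sum(kn == 0), 9)
})

test_that("the retention suite reports all criteria and never hides disagreement", {
  d <- hg_scale_data(generate_cohort(synthetic_config(n_subjects = 1200),
                                     seed = 1))
  ret <- retention_suite(data = d, max_k = 4, pa_reps = 300, cd_reps = 100,
                         seed = 1)
  expect_named(ret$suggestions, c("parallel_analysis", "ekc",
                                  "comparison_data", "ml_test", "bic", "rmsea"))
  expect_equal(ret$ekc$suggested_k, 2L)
  expect_equal(ret$comparison_data$suggested_k, 2L)
  expect_equal(sum(ret$observed_eigenvalues), 11)
  expect_type(ret$criteria_agree, "logical")
  # BIC and RMSEA table entries follow their definitions
  tab <- ret$ml_test_table
  expect_equal(tab$bic, tab$chi2 - tab$df * log(ret$n))
  expect_equal(tab$rmsea,
               sqrt(pmax(tab$chi2 - tab$df, 0) / (tab$df * (ret$n - 1))))
  # headline consensus breaks ties toward the smaller k
  expect_true(ret$headline_k <= max(ret$suggestions[c("parallel_analysis",
                                                      "ekc", "comparison_data")]))
})

test_that("identity-structured noise retains at most one factor everywhere", {
  set.seed(77)
  X <- matrix(rnorm(800 * 8), 800, 8)
  colnames(X) <- paste0("v", 1:8)
  ret <- retention_suite(data = X, max_k = 3, pa_reps = 300, cd_reps = 100,
                         seed = 5)
  expect_lte(ret$parallel_analysis$suggested_k, 1)
  expect_lte(ret$ekc$suggested_k, 1)
  expect_lte(ret$comparison_data$suggested_k, 1)
  expect_equal(ret$headline_k, 0L)
})

test_that("bootstrap loading intervals separate real from null loadings", {
  X <- factor_data(400, L2, Phi2, seed = 9)
  colnames(X) <- paste0("v", 1:11)
  ci <- loading_confidence_intervals(X, k = 2, reps = 60, seed = 13)
  expect_equal(ci$reps_used, 60)
  # strong primary loadings are significant
  strong <- rbind(cbind(1:5, 1), cbind(6:11, 2))
  expect_true(all(ci$significant[strong]))
  # cross-loadings are true zeros: most intervals cover 0
  nulls <- rbind(cbind(1:5, 2), cbind(6:11, 1))
  expect_gte(sum(!ci$significant[nulls]), 9)
  expect_error(loading_confidence_intervals(X, k = 2, reps = 0, seed = 1),
               "positive")
  expect_error(loading_confidence_intervals(rnorm(50), k = 1, reps = 10,
                                            seed = 1), "raw data")
})

test_that("factor alignment undoes permutation and reflection", {
  ref <- cbind(c(0.8, 0.7, 0.1, 0), c(0, 0.1, 0.7, 0.8))
  boot <- cbind(-ref[, 2], ref[, 1]) + matrix(rnorm(8, sd = 0.02), 4, 2)
  Phi <- matrix(c(1, -0.4, -0.4, 1), 2)
  al <- hazescore:::align_factors(ref, boot, Phi)
  expect_lt(max(abs(al$pattern - ref)), 0.1)
  expect_equal(al$Phi[1, 2], 0.4)
})
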