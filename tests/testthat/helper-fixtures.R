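# Fixtures built in code: blank response tables, a hand-scored cohort,
# and latent-factor data generators used across test files.

# a complete response table with every item at `fill`
blank_table <- function(n, fill = 0L) {
  df <- data.frame(subject_id = sprintf("T%03d", seq_len(n)),
                   group = "school", gender = "female", age_years = 10)
  for (it in paste0("item", 1:18)) df[[it]] <- fill
  for (d in c("computer", "game_console", "portable_console", "mobile_phone"))
    df[[paste0("freq_", d)]] <- fill
  df$weekday_minutes <- 0
  df$weekend_minutes <- 0
  df
}

# six subjects covering every classification outcome, scored by hand:
#   s1 all-zero               -> IGD none,          HG FALSE
#   s2 five criteria endorsed -> IGD full,          HG FALSE
#   s3 items 11+16 endorsed   -> IGD subclinical,   HG TRUE (c2, c4)
#   s4 daily mobile, 120 min  -> IGD none,          HG TRUE (c1)
#   s5 4 criteria + 1 unknown -> IGD indeterminate, HG FALSE
#   s6 item11 missing only    -> IGD none,          HG indeterminate
hand_cohort <- function() {
  df <- blank_table(6)
  df$subject_id <- paste0("s", 1:6)
  df[2, paste0("item", 1:5)] <- 3L          # preoccupation, tolerance,
                                            # withdrawal, loss of control,
                                            # escape: one item each
  df[3, c("item11", "item16")] <- 3L
  df[4, "freq_mobile_phone"] <- 6L
  df[4, c("weekday_minutes", "weekend_minutes")] <- 120
  df[5, paste0("item", 1:4)] <- 3L
  df[5, c("item5", "item17")] <- NA_integer_
  df[6, "item11"] <- NA_integer_
  df
}

# continuous latent-factor data with exact loadings (no thresholding)
factor_data <- function(n, loadings, Phi = diag(ncol(loadings)), seed) {
  set.seed(seed)
  k <- ncol(loadings)
  p <- nrow(loadings)
  Fm <- matrix(rnorm(n * k), n, k) %*% chol(Phi)
  uni <- sqrt(pmax(1 - rowSums((loadings %*% Phi) * loadings), 0))
  Fm %*% t(loadings) + matrix(rnorm(n * p), n, p) %*% diag(uni)
}

expect_tv_equal <- function(object, expected) {
  expect_identical(is.na(object), is.na(expected))
  expect_identical(object[!is.na(object)], expected[!is.na(expected)])
}
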