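#' Canonical order of the 11 Hazardous Gaming scale variables
#'
#' Four device frequencies, average daily gaming time, and the six
#' disorder items entering the Hazardous Gaming criteria.
#' @export
HG_SCALE_VARS <- c("computer", "game_console", "portable_console",
                   "mobile_phone", "gaming_time",
                   "item11", "item15", "item6", "item14", "item16", "item18")

#' Extract the 11-variable Hazardous Gaming scale data
#'
#' Builds the numeric matrix underlying the item/reliability/factor
#' analyses: the four device-frequency items, the derived average daily
#' gaming time, and items 11, 15, 6, 14, 16, 18, in the canonical
#' [HG_SCALE_VARS] order. Missing values are preserved.
#'
#' @inheritParams score_cohort
#' @return data.frame with 11 numeric columns.
#' @export
hg_scale_data <- function(table, codebook = default_codebook()) {
  fcols <- vapply(DEVICES, function(d)
    codebook$item_id[codebook$role == "frequency_item" & codebook$criterion == d],
    character(1))
  out <- data.frame(
    computer = table[[fcols["computer"]]],
    game_console = table[[fcols["game_console"]]],
    portable_console = table[[fcols["portable_console"]]],
    mobile_phone = table[[fcols["mobile_phone"]]],
    gaming_time = average_daily_time(table$weekday_minutes,
                                     table$weekend_minutes),
    item11 = table$item11, item15 = table$item15, item6 = table$item6,
    item14 = table$item14, item16 = table$item16, item18 = table$item18
  )
  out[, HG_SCALE_VARS]
}

#' Item difficulty
#'
#' Difficulty of an ordinal item is its mean divided by the scale
#' maximum, so it lies in \[0, 1\].
#'
#' @param mean item mean.
#' @param scale_max scale maximum (3 for disorder items, 6 for frequency
#'   items).
#' @return difficulty p in \[0,1\].
#' @export
item_difficulty <- function(mean, scale_max) {
  if (any(scale_max <= 0)) stop_hz("scale_max must be positive")
  if (any(mean < 0 | mean > scale_max, na.rm = TRUE))
    stop_hz("item mean must lie in [0, scale_max]")
  mean / scale_max
}

#' Difficulty analogue for gaming time
#'
#' Gaming time has no scale maximum; its tabulated difficulty is the
#' mean divided by the excessive-time threshold. This is a non-standard
#' index (a mean above the threshold exceeds 1) and is flagged as such
#' in report output.
#'
#' @param mean_minutes mean daily gaming time.
#' @param threshold_minutes excessive-time threshold, default 115.
#' @return mean/threshold.
#' @export
gaming_time_difficulty <- function(mean_minutes, threshold_minutes = 115) {
  if (any(threshold_minutes <= 0)) stop_hz("threshold must be positive")
  mean_minutes / threshold_minutes
}

#' Corrected item-total discrimination on z-standardized variables
#'
#' Because the 11 scale variables are on different scales (0--3, 0--6,
#' minutes), each variable is z-standardized before computing the
#' part-whole corrected item-total correlation: the Pearson correlation
#' of each standardized variable with the sum of the other ten, on
#' complete cases.
#'
#' @param data data.frame/matrix of the scale variables (typically
#'   [hg_scale_data()] output).
#' @return named numeric vector of discriminations; a zero-variance item
#'   yields `NA` with a warning.
#' @export
item_discrimination <- function(data) {
  x <- as.matrix(data)
  cc <- stats::complete.cases(x)
  if (sum(cc) < 3) stop_hz("need >= 3 complete cases for discrimination")
  x <- x[cc, , drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance item(s): ", toString(colnames(x)[sds == 0]),
            "; discrimination undefined", call. = FALSE)
  z <- scale(x)
  p <- ncol(z)
  out <- vapply(seq_len(p), function(j) {
    if (sds[j] == 0) return(NA_real_)
    tot <- rowSums(z[, -j, drop = FALSE], na.rm = FALSE)
    stats::cor(z[, j], tot)
  }, numeric(1))
  names(out) <- colnames(x)
  out
}

#' Pairwise-deletion Pearson correlation matrix
#'
#' Pearson correlations on pairwise-complete observations, with the
#' per-pair number of observations recorded (the analyses keep every
#' subject usable for each pair rather than listwise-deleting).
#'
#' @param data data.frame/matrix of numeric variables.
#' @return list of class `pairwise_correlations` with `r` (correlations,
#'   unit diagonal), `pair_n` (pairwise non-missing counts) and
#'   `variables`. Constant-variable cells are `NA` with a warning.
#' @export
pairwise_correlations <- function(data) {
  x <- as.matrix(data)
  obs <- !is.na(x)
  pair_n <- crossprod(obs)
  if (any(pair_n[upper.tri(pair_n)] < 3))
    stop_hz("fewer than 3 pairwise-complete observations for some pair")
  suppressWarnings(r <- stats::cor(x, use = "pairwise.complete.obs"))
  if (anyNA(r))
    warning("constant variable within some pair; correlation undefined",
            call. = FALSE)
  diag(r) <- 1
  structure(list(r = r, pair_n = pair_n, variables = colnames(x)),
            class = "pairwise_correlations")
}

#' Standardized Cronbach's alpha
#'
#' Because the scale mixes response formats, reliability is computed on
#' the correlation (not covariance) metric:
#' `alpha = k * mean_r / (1 + (k - 1) * mean_r)` with `mean_r` the mean
#' of the k(k-1)/2 inter-item correlations.
#'
#' @param x either a `pairwise_correlations` object, a correlation
#'   matrix, or a raw data.frame/matrix (then complete cases are used,
#'   mirroring a listwise reliability run).
#' @return list of class `reliability_result`: `standardized_alpha`, `k`,
#'   `mean_r`, `n_complete` (`NA` for matrix input).
#' @export
standardized_alpha <- function(x) {
  n_complete <- NA_integer_
  if (inherits(x, "pairwise_correlations")) {
    R <- x$r
  } else if (is.matrix(x) && nrow(x) == ncol(x) &&
             max(abs(diag(x) - 1)) < 1e-8) {
    R <- x
  } else {
    m <- as.matrix(x)
    cc <- stats::complete.cases(m)
    n_complete <- sum(cc)
    if (n_complete < 3) stop_hz("need >= 3 complete cases")
    R <- stats::cor(m[cc, , drop = FALSE])
  }
  k <- ncol(R)
  if (k < 2) stop_hz("alpha needs at least 2 items")
  off <- R[upper.tri(R)]
  if (anyNA(off)) stop_hz("alpha needs a complete correlation matrix")
  mean_r <- mean(off)
  structure(list(standardized_alpha = k * mean_r / (1 + (k - 1) * mean_r),
                 k = k, mean_r = mean_r, n_complete = n_complete),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Standardized Cronbach's alpha = %.3f (k = %d, mean r = %.3f%s)\n",
              x$standardized_alpha, x$k, x$mean_r,
              if (is.na(x$n_complete)) "" else
                sprintf(", n complete = %d", x$n_complete)))
  invisible(x)
}

#' Descriptive item statistics for the Hazardous Gaming scale
#'
#' Per-variable n, mean, SD, difficulty and corrected item-total
#' discrimination, in the layout of a standard item-analysis table.
#' Gaming time uses the mean/threshold difficulty analogue and is
#' flagged `nonstandard_difficulty`.
#'
#' @inheritParams score_cohort
#' @param threshold_minutes excessive-time threshold used for the
#'   gaming-time difficulty analogue.
#' @return data.frame: variable, n, mean, sd, difficulty,
#'   discrimination, nonstandard_difficulty.
#' @export
item_statistics <- function(table, codebook = default_codebook(),
                            threshold_minutes = 115) {
  d <- hg_scale_data(table, codebook)
  scale_max <- c(rep(6, 4), NA, rep(3, 6))
  disc <- item_discrimination(d)
  out <- data.frame(
    variable = HG_SCALE_VARS,
    n = colSums(!is.na(d)),
    mean = colMeans(as.matrix(d), na.rm = TRUE),
    sd = apply(d, 2, stats::sd, na.rm = TRUE),
    row.names = NULL
  )
  out$difficulty <- ifelse(
    is.na(scale_max),
    gaming_time_difficulty(out$mean, threshold_minutes),
    item_difficulty(out$mean, ifelse(is.na(scale_max), Inf, scale_max)))
  out$discrimination <- unname(disc)
  out$nonstandard_difficulty <- is.na(scale_max)
  out
}

#' Device-frequency distribution table
#'
#' Counts and shares per response category (0 "never" .. 6 "daily") for
#' each of the four device-frequency items.
#'
#' @inheritParams score_cohort
#' @return data.frame: device, category (0--6), count, share (of the
#'   device's non-missing n).
#' @export
device_frequency_table <- function(table, codebook = default_codebook()) {
  fcols <- vapply(DEVICES, function(d)
    codebook$item_id[codebook$role == "frequency_item" & codebook$criterion == d],
    character(1))
  do.call(rbind, lapply(DEVICES, function(d) {
    v <- table[[fcols[d]]]
    n <- sum(!is.na(v))
    cnt <- vapply(0:6, function(c) sum(v == c, na.rm = TRUE), integer(1))
    data.frame(device = d, category = 0:6, count = cnt, share = cnt / n)
  }))
}
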