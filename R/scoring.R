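#' Average daily gaming time
#'
#' Combines parent-estimated weekday and weekend gaming minutes into an
#' average daily time: `(5 * weekday + 2 * weekend) / 7`. Missing input
#' propagates to a missing result; negative input is an error.
#'
#' @param weekday_minutes,weekend_minutes nonnegative minutes (vectors
#'   recycle as usual).
#' @return average daily minutes, `NA` where either input is missing.
#' @export
average_daily_time <- function(weekday_minutes, weekend_minutes) {
  if (any(weekday_minutes < 0, na.rm = TRUE) ||
      any(weekend_minutes < 0, na.rm = TRUE))
    stop_hz("gaming times must be nonnegative")
  (5 * weekday_minutes + 2 * weekend_minutes) / 7
}

#' Excessive-gaming-time threshold (90th percentile)
#'
#' Gaming time at or above the sample's 90th percentile counts as
#' excessive. The percentile uses linear interpolation between order
#' statistics (quantile type 7); the rule name is recorded in the result
#' so reports can state it. With fewer than 10 usable values the sample
#' quantile is meaningless and an error directs the caller to a fixed
#' override (115 minutes/day is the reference cut-off from the original
#' mixed school/clinic calibration sample).
#'
#' @param times average daily minutes; missings are dropped.
#' @param prob percentile, default 0.9.
#' @return list with `minutes`, `prob`, `rule` ("type7_linear_interpolation"),
#'   `n` (values used).
#' @export
excessive_time_threshold <- function(times, prob = 0.9) {
  x <- times[!is.na(times)]
  if (length(x) < 10)
    stop_hz(paste("need >= 10 non-missing gaming times to estimate a percentile;",
                  "supply a fixed threshold override (reference value: 115 min/day)"))
  list(minutes = unname(stats::quantile(x, prob, type = 7)),
       prob = prob, rule = "type7_linear_interpolation", n = length(x))
}

#' Score one IGD criterion from its item pair
#'
#' A criterion is endorsed when either of its two items carries the
#' highest rating (3, "strongly agree"). With missing data the result is
#' three-valued: `TRUE` if any observed item is 3, `FALSE` if both items
#' are observed below 3, `NA` (indeterminate) otherwise.
#'
#' @param item_a,item_b ordinal responses 0--3, `NA` allowed; vectorized.
#' @return logical vector (`NA` = indeterminate).
#' @export
score_igd_criterion <- function(item_a, item_b) {
  if (any(c(item_a, item_b) < 0 | c(item_a, item_b) > 3, na.rm = TRUE))
    stop_hz("disorder-item responses must lie in 0..3")
  (item_a == 3) | (item_b == 3)
}

#' Classify (subclinical) IGD from nine criterion outcomes
#'
#' At least five endorsed criteria give a tentative IGD classification;
#' two to four give subclinical IGD; zero or one gives none. A class is
#' emitted only when every completion of the indeterminate criteria
#' yields the same class; otherwise the subject is indeterminate.
#'
#' @param criteria logical matrix (subjects x 9) or vector of length 9;
#'   `NA` = indeterminate criterion.
#' @return data.frame with `n_endorsed` (criteria endorsed; `NA` when the
#'   count itself is ambiguous across completions) and `igd_class`
#'   (factor: none, subclinical, full, indeterminate).
#' @export
classify_igd <- function(criteria) {
  if (is.vector(criteria)) criteria <- matrix(criteria, nrow = 1)
  if (ncol(criteria) != 9) stop_hz("classify_igd needs 9 criterion columns")
  n_true <- rowSums(criteria, na.rm = TRUE)
  n_na <- rowSums(is.na(criteria))
  cls <- function(k) ifelse(k >= 5, "full", ifelse(k >= 2, "subclinical", "none"))
  lo <- cls(n_true)          # all indeterminates resolved false
  hi <- cls(n_true + n_na)   # all resolved true
  out <- ifelse(lo == hi, lo, "indeterminate")
  data.frame(
    n_endorsed = ifelse(n_na == 0, n_true, NA_integer_),
    igd_class = factor(out, levels = c("none", "subclinical", "full",
                                       "indeterminate"))
  )
}

#' Hazardous Gaming criterion 1: excessive gaming time and frequency
#'
#' Endorsed when the child plays daily on at least one device (frequency
#' rating 6 on any of the four device items) AND the average daily gaming
#' time reaches the excessive-time threshold. Both conjuncts use
#' three-valued logic, so e.g. a missing gaming time with no daily device
#' still yields a determinate `FALSE`.
#'
#' @param device_frequencies matrix (subjects x 4) or length-4 vector of
#'   0--6 ratings, `NA` allowed.
#' @param avg_time average daily minutes.
#' @param threshold_minutes excessive-time cut-off (inclusive), default 115.
#' @return logical vector (`NA` = indeterminate).
#' @export
score_hg_c1 <- function(device_frequencies, avg_time, threshold_minutes = 115) {
  if (is.vector(device_frequencies))
    device_frequencies <- matrix(device_frequencies, nrow = 1)
  if (any(device_frequencies < 0 | device_frequencies > 6, na.rm = TRUE))
    stop_hz("device frequencies must lie in 0..6")
  daily <- device_frequencies == 6
  any_daily <- apply(daily, 1, function(r) any(r))  # Kleene any()
  any_daily & (avg_time >= threshold_minutes)
}

#' Hazardous Gaming criterion 2: neglect of other activities
#'
#' Endorsed when the "give up other activities" IGD criterion is met,
#' i.e. the highest rating on item 11 or item 15.
#'
#' @param item11,item15 ordinal responses 0--3.
#' @return logical vector (`NA` = indeterminate).
#' @export
score_hg_c2 <- function(item11, item15) score_igd_criterion(item11, item15)

#' Hazardous Gaming criterion 4: adverse consequences of gaming
#'
#' Endorsed when either the "continue despite problems" criterion (items
#' 6, 14) or the "risk/lose" criterion (items 16, 18) is met — i.e. the
#' highest rating on at least one of the four items.
#'
#' @param item6,item14,item16,item18 ordinal responses 0--3.
#' @return logical vector (`NA` = indeterminate).
#' @export
score_hg_c4 <- function(item6, item14, item16, item18) {
  v <- c(item6, item14, item16, item18)
  if (any(v < 0 | v > 3, na.rm = TRUE))
    stop_hz("disorder-item responses must lie in 0..3")
  (item6 == 3) | (item14 == 3) | (item16 == 3) | (item18 == 3)
}

#' Hazardous Gaming flag
#'
#' The assessable criteria are linked by OR (ICD-11 links the Hazardous
#' Gaming risk sources disjunctively). Criterion 3 ("risky behaviors
#' associated with gaming or its context") is not assessable with the
#' 18-item instrument; it is carried as always-indeterminate and never
#' enters the disjunction unless extension items are supplied (see
#' [score_cohort()]).
#'
#' @param c1,c2,c4 logical criterion outcomes (`NA` = indeterminate).
#' @param c3 optional extension-criterion outcomes; default all `NA`
#'   and excluded from the OR.
#' @return logical vector (`NA` = indeterminate).
#' @export
classify_hg <- function(c1, c2, c4, c3 = NULL) {
  flag <- c1 | c2 | c4
  if (!is.null(c3) && !all(is.na(c3))) flag <- flag | c3
  flag
}

#' Score a cohort: IGD classes, Hazardous Gaming flags, gaming time
#'
#' Applies the full diagnostic scoring to every subject: the nine IGD
#' criteria (two items each, highest rating endorses), the IGD /
#' subclinical IGD classification, the three assessable Hazardous Gaming
#' criteria and their OR. Indeterminate outcomes are carried explicitly,
#' never dropped; the cohort summary reports determinate counts per
#' construct ("valid data" denominators).
#'
#' @param table a `csas_responses` data.frame.
#' @param codebook a `csas_codebook`.
#' @param threshold_minutes fixed excessive-time cut-off in minutes
#'   (default 115, the reference calibration); set to `NULL` to estimate
#'   the in-sample 90th percentile instead.
#' @param threshold_percentile percentile used when `threshold_minutes`
#'   is `NULL`.
#' @param extension_items optional character vector of 4 column names
#'   carrying criterion-3 extension items (0--3 scale, highest rating
#'   endorses); when supplied, criterion 3 enters the OR.
#' @return list of class `hg_scores` with `records` (one row per subject)
#'   and `summary` (list: n, determinate counts, class counts, threshold
#'   used).
#' @export
score_cohort <- function(table, codebook = default_codebook(),
                         threshold_minutes = 115,
                         threshold_percentile = 0.9,
                         extension_items = NULL) {
  avg <- average_daily_time(table$weekday_minutes, table$weekend_minutes)
  if (is.null(threshold_minutes)) {
    thr <- excessive_time_threshold(avg, threshold_percentile)
  } else {
    if (threshold_minutes <= 0) stop_hz("threshold must be positive")
    thr <- list(minutes = threshold_minutes, prob = NA_real_,
                rule = "fixed_override", n = NA_integer_)
  }

  igd <- codebook[codebook$role == "igd_item", ]
  crit <- sapply(IGD_CRITERIA, function(cr) {
    it <- igd$item_id[igd$criterion == cr]
    score_igd_criterion(table[[it[1]]], table[[it[2]]])
  })
  if (nrow(table) == 1) crit <- matrix(crit, nrow = 1,
                                       dimnames = list(NULL, IGD_CRITERIA))
  igd_cls <- classify_igd(crit)

  fcols <- vapply(DEVICES, function(d)
    codebook$item_id[codebook$role == "frequency_item" & codebook$criterion == d],
    character(1))
  freq <- as.matrix(table[, fcols, drop = FALSE])
  c1 <- score_hg_c1(freq, avg, thr$minutes)
  c2 <- score_hg_c2(table$item11, table$item15)
  c4 <- score_hg_c4(table$item6, table$item14, table$item16, table$item18)
  c3 <- rep(NA, nrow(table))
  if (!is.null(extension_items)) {
    if (length(extension_items) != 4 ||
        !all(extension_items %in% names(table)))
      stop_hz("extension_items must name 4 columns present in the table")
    ext <- as.matrix(table[, extension_items, drop = FALSE])
    if (any(ext < 0 | ext > 3, na.rm = TRUE))
      stop_hz("extension items must lie in 0..3")
    hit <- ext == 3
    c3 <- apply(hit, 1, function(r) any(r))
  }
  hg <- classify_hg(c1, c2, c4, c3 = if (is.null(extension_items)) NULL else c3)

  records <- data.frame(
    subject_id = table$subject_id,
    group = table$group,
    gender = table$gender,
    age_years = table$age_years,
    avg_daily_minutes = avg,
    crit, check.names = FALSE
  )
  records$igd_criteria_met <- igd_cls$n_endorsed
  records$igd_class <- igd_cls$igd_class
  records$hg_c1_excessive <- c1
  records$hg_c2_neglect <- c2
  records$hg_c3_risky_context <- c3
  records$hg_c4_adverse <- c4
  records$hg_flag <- hg

  summary <- list(
    n = nrow(records),
    threshold = thr,
    igd_determinate_n = sum(records$igd_class != "indeterminate"),
    hg_determinate_n = sum(!is.na(records$hg_flag)),
    igd_class_counts = table(records$igd_class),
    hg_positive = sum(records$hg_flag, na.rm = TRUE)
  )
  structure(list(records = records, summary = summary), class = "hg_scores")
}

#' @export
print.hg_scores <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Scored cohort: %d subjects\n", s$n))
  cat(sprintf("  excessive-time threshold: %.1f min (%s)\n",
              s$threshold$minutes, s$threshold$rule))
  cat(sprintf("  IGD determinate: %d; classes: %s\n", s$igd_determinate_n,
              paste(names(s$igd_class_counts), as.integer(s$igd_class_counts),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  HG determinate: %d; HG positive: %d\n",
              s$hg_determinate_n, s$hg_positive))
  invisible(x)
}
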