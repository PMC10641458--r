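#' Prevalence estimate with a Wald confidence interval
#'
#' Proportion `count / n_valid` with the normal-approximation interval
#' `p +/- z * sqrt(p (1 - p) / n)`, clipped to \[0, 1\]. A Wilson
#' interval is available behind `method = "wilson"`.
#'
#' @param count positive cases among the valid subjects.
#' @param n_valid subjects with determinate data for the construct.
#' @param level confidence level, default 0.95.
#' @param label optional construct label carried into the result.
#' @param method `"wald"` (default) or `"wilson"`.
#' @return list of class `prevalence_estimate`: `label`, `count`,
#'   `n_valid`, `proportion`, `ci_low`, `ci_high`, `level`, `method`.
#' @export
prevalence_ci <- function(count, n_valid, level = 0.95, label = NULL,
                          method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (n_valid <= 0) stop_hz("n_valid must be positive")
  if (count < 0 || count > n_valid)
    stop_hz("count must lie in [0, n_valid]")
  p <- count / n_valid
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n_valid)
    lo <- max(p - half, 0)
    hi <- min(p + half, 1)
  } else {
    den <- 1 + z^2 / n_valid
    ctr <- (p + z^2 / (2 * n_valid)) / den
    half <- z * sqrt(p * (1 - p) / n_valid + z^2 / (4 * n_valid^2)) / den
    lo <- max(ctr - half, 0)
    hi <- min(ctr + half, 1)
  }
  structure(list(label = label, count = count, n_valid = n_valid,
                 proportion = p, ci_low = lo, ci_high = hi,
                 level = level, method = method),
            class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("%s%.1f%% (%.0f%% CI = %.1f-%.1f; n = %d of %d)\n",
              if (is.null(x$label)) "" else paste0(x$label, ": "),
              100 * x$proportion, 100 * x$level, 100 * x$ci_low,
              100 * x$ci_high, x$count, x$n_valid))
  invisible(x)
}

#' Cross-classify two binary flags, excluding indeterminates
#'
#' Builds the 2x2 contingency table over subjects determinate on both
#' constructs; indeterminate (`NA`) subjects are counted and excluded,
#' never silently dropped.
#'
#' @param flags_a,flags_b equal-length logical vectors (`NA` =
#'   indeterminate).
#' @param labels length-2 character vector naming the constructs.
#' @return list: `table` (2x2, rows = a, cols = b, TRUE first),
#'   `n_used`, `n_excluded`.
#' @export
crosstab <- function(flags_a, flags_b, labels = c("a", "b")) {
  if (length(flags_a) != length(flags_b))
    stop_hz("classification vectors must have equal length")
  keep <- !is.na(flags_a) & !is.na(flags_b)
  a <- factor(flags_a[keep], levels = c(TRUE, FALSE))
  b <- factor(flags_b[keep], levels = c(TRUE, FALSE))
  tab <- table(a, b, dnn = labels)
  list(table = unclass(tab), n_used = sum(keep), n_excluded = sum(!keep))
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` with the
#' large-sample standard error under independence and the corresponding
#' z-test. The qualitative band follows the conventional scale (slight
#' <= 0.20, fair 0.21--0.40, moderate 0.41--0.60, substantial
#' 0.61--0.80, almost perfect > 0.80). With a degenerate margin kappa is
#' still reported but the test is flagged unavailable.
#'
#' @param tab 2x2 count matrix.
#' @return list of class `agreement_result`: `table`, `po`, `pe`,
#'   `kappa`, `se_kappa`, `z`, `p_value`, `interpretation`,
#'   `test_available`.
#' @export
cohens_kappa <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stop_hz("cohens_kappa expects a 2x2 table")
  n <- sum(tab)
  if (n <= 0) stop_hz("empty table")
  prop <- tab / n
  po <- sum(diag(prop))
  rs <- rowSums(prop)
  cs <- colSums(prop)
  pe <- sum(rs * cs)
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  degenerate <- any(rs == 0) || any(cs == 0) || pe >= 1
  if (!degenerate) {
    # H0 (independence) standard error, Fleiss large-sample form
    se0 <- sqrt((pe + pe^2 - sum(rs * cs * (rs + cs))) / n) / (1 - pe)
    z <- kappa / se0
    pval <- 2 * stats::pnorm(-abs(z))
  } else {
    se0 <- NA_real_; z <- NA_real_; pval <- NA_real_
  }
  band <- cut(kappa, c(-Inf, 0.20, 0.40, 0.60, 0.80, Inf),
              labels = c("slight", "fair", "moderate", "substantial",
                         "almost perfect"))
  structure(list(table = tab, po = po, pe = pe, kappa = kappa,
                 se_kappa = se0, z = z, p_value = pval,
                 interpretation = as.character(band),
                 test_available = !degenerate),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.2f (%s); po = %.3f, pe = %.3f",
              x$kappa, x$interpretation, x$po, x$pe))
  if (x$test_available)
    cat(sprintf("; z = %.2f, p = %.3g\n", x$z, x$p_value))
  else cat("; significance test unavailable (degenerate margin)\n")
  invisible(x)
}

#' Overlap of Hazardous Gaming with (subclinical) IGD
#'
#' Cross-classifies the Hazardous Gaming flag against the three-level
#' IGD class over subjects determinate on both constructs, and reports
#' the headline overlap shares with their construct-specific
#' denominators: the share of HG-positive children with neither IGD nor
#' subclinical IGD ("HG only"), the share of IGD children also meeting
#' HG, and the share of subclinical-IGD children also meeting HG.
#' Cohen's kappa is computed for HG vs IGD, HG vs subclinical IGD, and
#' HG vs any (subclinical or full) IGD.
#'
#' @param records classification records from [score_cohort()].
#' @return list of class `overlap_summary`: `cells` (2x3 counts),
#'   `n_both_determinate`, `n_excluded`, `shares` (the three headline
#'   shares as [prevalence_ci()] objects), `kappa` (list of three
#'   [cohens_kappa()] results).
#' @export
overlap_summary <- function(records) {
  hg <- records$hg_flag
  cls <- records$igd_class
  keep <- !is.na(hg) & cls != "indeterminate"
  hgk <- hg[keep]
  clk <- droplevels(factor(cls[keep], levels = c("none", "subclinical", "full")))
  cells <- table(hg = factor(hgk, levels = c(TRUE, FALSE)),
                 igd = factor(clk, levels = c("none", "subclinical", "full")))

  share <- function(count, denom, label) {
    if (denom == 0) return(NULL)
    prevalence_ci(count, denom, label = label)
  }
  n_hg <- sum(hgk)
  n_igd <- sum(clk == "full")
  n_sub <- sum(clk == "subclinical")
  shares <- list(
    hg_only = share(sum(hgk & clk == "none"), n_hg,
                    "HG positive with neither IGD nor subclinical IGD"),
    igd_meeting_hg = share(sum(hgk & clk == "full"), n_igd,
                           "IGD also meeting HG"),
    subclinical_meeting_hg = share(sum(hgk & clk == "subclinical"), n_sub,
                                   "subclinical IGD also meeting HG")
  )
  igd_na <- function(pos) ifelse(cls == "indeterminate", NA, cls %in% pos)
  kap <- list(
    hg_vs_igd = cohens_kappa(crosstab(hg, igd_na("full"))$table),
    hg_vs_subclinical = cohens_kappa(crosstab(hg, igd_na("subclinical"))$table),
    hg_vs_any_igd = cohens_kappa(crosstab(hg, igd_na(c("subclinical", "full")))$table)
  )
  structure(list(cells = unclass(cells), n_both_determinate = sum(keep),
                 n_excluded = sum(!keep), shares = shares, kappa = kap),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("Overlap summary (n = %d determinate on both, %d excluded)\n",
              x$n_both_determinate, x$n_excluded))
  print(x$cells)
  for (s in x$shares) if (!is.null(s)) print(s)
  for (nm in names(x$kappa)) {
    cat(nm, ": ")
    print(x$kappa[[nm]])
  }
  invisible(x)
}

#' Prevalence by subgroup
#'
#' Construct prevalence with confidence intervals within each level of a
#' metadata field (e.g. gender or group). Subjects indeterminate on the
#' construct are excluded from that level's denominator; empty levels
#' yield no estimate and are flagged.
#'
#' @param records classification records from [score_cohort()].
#' @param flag name of a logical record column (e.g. `"hg_flag"`), or a
#'   logical vector.
#' @param by name of the grouping metadata column.
#' @param level confidence level.
#' @return data.frame: group, count, n_valid, proportion, ci_low,
#'   ci_high (NA rows for empty/indeterminate-only levels).
#' @export
subgroup_prevalence <- function(records, flag = "hg_flag", by, level = 0.95) {
  if (!by %in% names(records)) stop_hz("grouping field '%s' not found", by)
  f <- if (is.character(flag)) records[[flag]] else flag
  g <- records[[by]]
  out <- lapply(unique(g), function(lv) {
    fi <- f[g == lv]
    nv <- sum(!is.na(fi))
    if (nv == 0)
      return(data.frame(group = lv, count = NA_integer_, n_valid = 0L,
                        proportion = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_))
    est <- prevalence_ci(sum(fi, na.rm = TRUE), nv, level = level)
    data.frame(group = lv, count = est$count, n_valid = est$n_valid,
               proportion = est$proportion, ci_low = est$ci_low,
               ci_high = est$ci_high)
  })
  do.call(rbind, out)
}
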