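#' Run the full analysis pipeline
#'
#' Orchestrates scoring, item analysis, reliability, EFA with
#' multi-criterion retention, and the prevalence/overlap/agreement
#' analyses, writing a report bundle (CSV + JSON) and a run manifest.
#' Identical config and seed give identical machine-readable outputs.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{responses, codebook}{paths to input CSVs, or}
#'     \item{synthetic}{a [synthetic_config()] (exactly one input
#'       source must be given)}
#'     \item{seed}{integer; required whenever any stochastic step runs}
#'     \item{threshold_minutes}{excessive-time cut-off (default 115);
#'       `NULL` to estimate the 90th percentile in-sample}
#'     \item{max_k, pa_reps, cd_reps, boot_reps}{EFA settings
#'       (defaults 5, 1000, 250, 0 = no bootstrap CIs)}
#'     \item{out_dir}{output directory}
#'     \item{precision}{decimals for report CSVs (default 2)}
#'   }
#' @return list of class `pipeline_result` with all stage outputs
#'   (invisibly writes the bundle when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  has_files <- !is.null(cfg$responses)
  has_syn <- !is.null(cfg$synthetic)
  if (has_files == has_syn)
    stop_hz("exactly one input source required: responses path or synthetic config")
  if (is.null(cfg$seed)) stop_hz("config$seed is required")
  seed <- as.integer(cfg$seed)
  threshold <- if ("threshold_minutes" %in% names(cfg))
    cfg$threshold_minutes else 115
  max_k <- cfg$max_k %||% 5
  pa_reps <- cfg$pa_reps %||% 1000
  cd_reps <- cfg$cd_reps %||% 250
  boot_reps <- cfg$boot_reps %||% 0
  precision <- cfg$precision %||% 2

  codebook <- if (!is.null(cfg$codebook)) read_codebook(cfg$codebook)
  else default_codebook()
  tab <- if (has_files) read_responses(cfg$responses, codebook)
  else generate_cohort(cfg$synthetic, seed = seed)

  miss <- missingness_report(tab, codebook)
  scores <- score_cohort(tab, codebook, threshold_minutes = threshold)
  istats <- item_statistics(tab, codebook,
                            threshold_minutes = scores$summary$threshold$minutes)
  devfreq <- device_frequency_table(tab, codebook)
  d <- hg_scale_data(tab, codebook)
  pc <- pairwise_correlations(d)
  rel <- standardized_alpha(pc)
  n_eff <- mean(pc$pair_n[upper.tri(pc$pair_n)])
  adequacy <- adequacy_report(pc$r, round(n_eff))
  retention <- retention_suite(R = pc$r, n = n_eff, max_k = max_k,
                               pa_reps = pa_reps, cd_reps = cd_reps,
                               seed = seed)
  k <- max(retention$headline_k, 1)
  efa <- ml_efa(R = pc$r, n = n_eff, k = k)
  hord <- if (k >= 2) higher_order_factor(efa$Phi) else NULL
  cis <- if (boot_reps > 0)
    loading_confidence_intervals(d, k = k, reps = boot_reps, seed = seed)
  else NULL
  overlap <- overlap_summary(scores$records)
  prev <- list(
    hg = prevalence_ci(sum(scores$records$hg_flag, na.rm = TRUE),
                       sum(!is.na(scores$records$hg_flag)), label = "HG"),
    subclinical = prevalence_ci(
      sum(scores$records$igd_class == "subclinical"),
      scores$summary$igd_determinate_n, label = "subclinical IGD"),
    igd = prevalence_ci(sum(scores$records$igd_class == "full"),
                        scores$summary$igd_determinate_n, label = "IGD")
  )
  by_gender <- subgroup_prevalence(scores$records, "hg_flag", "gender")

  manifest <- list(
    package_version = as.character(utils::packageVersion("hazescore")),
    seed = seed,
    input = if (has_files) cfg$responses else "synthetic",
    n_subjects = nrow(tab),
    threshold = scores$summary$threshold,
    efa = list(max_k = max_k, pa_reps = pa_reps, cd_reps = cd_reps,
               boot_reps = boot_reps, rotation = "oblimin", gamma = 0,
               n_rule = "mean_pairwise", eigenvalue_convention = "correlation_matrix",
               headline_rule = "consensus_pa_cd_ekc_ties_smaller"),
    quantile_rule = "type7_linear_interpolation",
    correlations = "pearson_pairwise", alpha_input = "pairwise_correlations",
    ci_method = "wald", missing_data = "not_replaced"
  )

  res <- structure(list(
    table = tab, missingness = miss, scores = scores, item_stats = istats,
    device_frequencies = devfreq, correlations = pc, reliability = rel,
    adequacy = adequacy, retention = retention, efa = efa,
    higher_order = hord, loading_ci = cis, overlap = overlap,
    prevalence = prev, prevalence_by_gender = by_gender,
    manifest = manifest
  ), class = "pipeline_result")

  if (!is.null(cfg$out_dir)) write_bundle(res, cfg$out_dir, precision)
  res
}

write_bundle <- function(res, out_dir, precision = 2) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = FALSE, na = "")
  num <- function(df) {
    for (cl in names(df)) if (is.numeric(df[[cl]]))
      df[[cl]] <- round_half_up(df[[cl]], precision + 2)
    df
  }
  rec <- res$scores$records
  rec$igd_class <- as.character(rec$igd_class)
  for (cl in names(rec)) if (is.logical(rec[[cl]])) rec[[cl]] <- tv_chr(rec[[cl]])
  wcsv(rec, "classification_records.csv")
  wcsv(res$missingness$per_item, "missingness_per_item.csv")
  ist <- res$item_stats
  ist[c("mean", "sd", "difficulty", "discrimination")] <-
    lapply(ist[c("mean", "sd", "difficulty", "discrimination")],
           round_half_up, precision)
  wcsv(ist, "item_statistics.csv")
  wcsv(num(res$device_frequencies), "device_frequencies.csv")
  r <- round_half_up(res$correlations$r, precision)
  wcsv(data.frame(variable = rownames(r), r, check.names = FALSE),
       "interitem_correlations.csv")
  wcsv(data.frame(variable = rownames(res$correlations$pair_n),
                  res$correlations$pair_n, check.names = FALSE),
       "interitem_pair_n.csv")
  wcsv(data.frame(rank = seq_along(res$retention$observed_eigenvalues),
                  eigenvalue = res$retention$observed_eigenvalues,
                  pa_reference = res$retention$parallel_analysis$reference,
                  ekc_reference = res$retention$ekc$reference),
       "scree.csv")
  wcsv(num(res$retention$ml_test_table), "ml_fit_by_k.csv")
  pat <- res$efa$pattern_loadings
  wcsv(data.frame(variable = rownames(pat), round_half_up(pat, precision + 1),
                  check.names = FALSE), "pattern_loadings.csv")

  js <- list(
    manifest = res$manifest,
    reliability = unclass(res$reliability),
    adequacy = unclass(res$adequacy),
    retention_suggestions = as.list(res$retention$suggestions),
    headline_k = res$retention$headline_k,
    efa = list(k = res$efa$k, Phi = res$efa$Phi,
               ss_loadings = res$efa$ss_loadings,
               proportion_variance = res$efa$proportion_variance,
               chi2 = res$efa$chi2, df = res$efa$df,
               p_value = res$efa$p_value, bic = res$efa$bic,
               rmsea = res$efa$rmsea, heywood = res$efa$heywood),
    higher_order = if (!is.null(res$higher_order))
      unclass(res$higher_order),
    prevalence = lapply(res$prevalence, unclass),
    prevalence_by_gender = res$prevalence_by_gender,
    overlap = list(cells = res$overlap$cells,
                   n_both_determinate = res$overlap$n_both_determinate,
                   n_excluded = res$overlap$n_excluded,
                   shares = lapply(res$overlap$shares,
                                   function(s) if (!is.null(s)) unclass(s)),
                   kappa = lapply(res$overlap$kappa, function(k)
                     unclass(k)[c("po", "pe", "kappa", "se_kappa", "z",
                                  "p_value", "interpretation")]))
  )
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n===============\n")
  print(x$scores)
  print(x$reliability)
  cat(sprintf("KMO = %.2f; Bartlett chi2(%d) = %.1f\n",
              x$adequacy$kmo, x$adequacy$df, x$adequacy$chi2))
  print(x$retention)
  print(x$efa)
  if (!is.null(x$higher_order))
    cat(sprintf("Higher-order g-loadings: %s\n",
                paste(round(x$higher_order$g_loadings, 3), collapse = ", ")))
  for (p in x$prevalence) print(p)
  invisible(x)
}
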