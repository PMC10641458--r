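#' Published item statistics for the Hazardous Gaming scale
#'
#' The descriptive item statistics of the 11 scale variables (n, mean,
#' SD, difficulty, corrected item-total discrimination) as published for
#' the mixed school/clinic calibration cohort (N = 871 children aged
#' 8--12). These printed values serve as inputs: reliability worked
#' examples, generator calibration targets and desk-check oracles.
#'
#' @return data.frame with one row per scale variable.
#' @export
csas_reference_item_stats <- function() {
  utils::read.csv(system.file("extdata", "csas_hg_item_stats.csv",
                              package = "hazescore", mustWork = TRUE))
}

#' Published inter-item correlations of the Hazardous Gaming scale
#'
#' The 11 x 11 inter-item Pearson correlation matrix of the calibration
#' cohort (pairwise deletion; 2-decimal printed precision) together with
#' the per-pair observation counts.
#'
#' @return list of class `pairwise_correlations` with `r`, `pair_n` and
#'   `variables`.
#' @export
csas_reference_correlations <- function() {
  read_sq <- function(f) {
    d <- utils::read.csv(system.file("extdata", f, package = "hazescore",
                                     mustWork = TRUE), check.names = FALSE)
    m <- as.matrix(d[, -1])
    rownames(m) <- d$variable
    m
  }
  r <- read_sq("csas_hg_interitem_r.csv")
  pn <- read_sq("csas_hg_interitem_n.csv")
  structure(list(r = r, pair_n = pn, variables = rownames(r)),
            class = "pairwise_correlations")
}

#' Published device-frequency distribution
#'
#' Counts per response category (0 "never" .. 6 "daily") for the four
#' device-frequency items in the calibration cohort. Used as the
#' synthetic generator's marginal targets and for worked share examples.
#'
#' @return data.frame: category, label, one count column per device.
#' @export
csas_reference_device_frequencies <- function() {
  utils::read.csv(system.file("extdata", "csas_device_frequency_counts.csv",
                              package = "hazescore", mustWork = TRUE))
}
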