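# Bootstrap confidence intervals for pattern loadings, with factor
# alignment across refits (greedy Tucker-congruence matching plus sign
# fixing — bootstrap solutions are only identified up to column
# permutation and reflection).

tucker_congruence <- function(x, y) {
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

# match columns of `boot` to columns of `ref`; returns reordered,
# sign-fixed boot pattern (and Phi when given)
align_factors <- function(ref, boot, Phi = NULL) {
  k <- ncol(ref)
  C <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    C[i, j] <- tucker_congruence(ref[, i], boot[, j])
  perm <- integer(k)
  sgn <- numeric(k)
  A <- abs(C)
  for (step in seq_len(k)) {
    ij <- which(A == max(A), arr.ind = TRUE)[1, ]
    perm[ij[1]] <- ij[2]
    sgn[ij[1]] <- sign(C[ij[1], ij[2]])
    A[ij[1], ] <- -Inf
    A[, ij[2]] <- -Inf
  }
  sgn[sgn == 0] <- 1
  out <- sweep(boot[, perm, drop = FALSE], 2, sgn, `*`)
  if (!is.null(Phi)) {
    Phi <- Phi[perm, perm, drop = FALSE] * outer(sgn, sgn)
    return(list(pattern = out, Phi = Phi))
  }
  list(pattern = out)
}

#' Bootstrap confidence intervals for factor loadings
#'
#' Nonparametric bootstrap over subjects: rows are resampled with
#' replacement, the pairwise correlation matrix is recomputed, the
#' k-factor ML + oblimin solution refitted, factors aligned to the
#' full-sample solution by greedy Tucker-congruence matching with sign
#' fixing, and percentile intervals taken per loading. A loading is
#' "significant" when its interval excludes zero.
#'
#' @param data raw response data for the scale variables (matrix-only
#'   input cannot be bootstrapped).
#' @param k number of factors.
#' @param reps bootstrap replications (> 0).
#' @param level confidence level, default 0.95.
#' @param seed RNG seed.
#' @param gamma oblimin gamma.
#' @return list of class `loading_ci`: `estimate` (full-sample pattern),
#'   `lower`, `upper`, `significant`, `phi_ci` (intervals for the
#'   factor correlations), `reps_used` (failed refits are dropped).
#' @export
loading_confidence_intervals <- function(data, k, reps = 500, level = 0.95,
                                         seed, gamma = 0) {
  if (is.null(dim(data)))
    stop_hz("raw data (subjects x variables) required for the bootstrap")
  if (reps <= 0) stop_hz("reps must be positive")
  x <- as.matrix(data)
  nsub <- nrow(x)
  ref <- ml_efa(data = x, k = k, gamma = gamma)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p <- ncol(x)
  boots <- array(NA_real_, c(reps, p, k))
  phis <- array(NA_real_, c(reps, k, k))
  ok <- logical(reps)
  for (b in seq_len(reps)) {
    idx <- sample.int(nsub, nsub, replace = TRUE)
    fit <- try(ml_efa(data = x[idx, , drop = FALSE], k = k, gamma = gamma),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    al <- align_factors(ref$pattern_loadings, fit$pattern_loadings, fit$Phi)
    boots[b, , ] <- al$pattern
    phis[b, , ] <- al$Phi
    ok[b] <- TRUE
  }
  if (!any(ok)) stop_hz("all bootstrap refits failed")
  a <- (1 - level) / 2
  qs <- apply(boots[ok, , , drop = FALSE], c(2, 3), stats::quantile,
              probs = c(a, 1 - a), na.rm = TRUE)
  lower <- qs[1, , ]
  upper <- qs[2, , ]
  dimnames(lower) <- dimnames(upper) <- dimnames(ref$pattern_loadings)
  phi_q <- apply(phis[ok, , , drop = FALSE], c(2, 3), stats::quantile,
                 probs = c(a, 1 - a), na.rm = TRUE)
  structure(list(
    estimate = ref$pattern_loadings,
    lower = lower, upper = upper,
    significant = lower > 0 | upper < 0,
    phi = ref$Phi, phi_lower = phi_q[1, , ], phi_upper = phi_q[2, , ],
    level = level, reps_used = sum(ok)
  ), class = "loading_ci")
}

#' @export
print.loading_ci <- function(x, digits = 2, ...) {
  cat(sprintf("Bootstrap %.0f%% percentile intervals (%d replications)\n",
              100 * x$level, x$reps_used))
  for (j in seq_len(ncol(x$estimate))) {
    cat(colnames(x$estimate)[j], ":\n")
    df <- data.frame(loading = round(x$estimate[, j], digits),
                     lower = round(x$lower[, j], digits),
                     upper = round(x$upper[, j], digits),
                     significant = x$significant[, j])
    print(df)
  }
  invisible(x)
}
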