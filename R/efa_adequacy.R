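#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is an identity (no correlations to
#' factor). `chi2 = -(n - 1 - (2p + 5)/6) * ln det(R)` with
#' `df = p(p-1)/2`.
#'
#' @param R correlation matrix.
#' @param n sample size (must exceed the number of variables).
#' @return list: `chi2`, `df`, `p_value`, `n`, `p` (number of variables).
#' @export
bartlett_test <- function(R, n) {
  check_corr_matrix(R)
  p <- ncol(R)
  if (n <= p) stop_hz("sample size must exceed the number of variables")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * determinant(R, logarithm = TRUE)$modulus[1]
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE), n = n, p = p)
}

#' Kaiser-Meyer-Olkin sampling adequacy (overall and per item)
#'
#' Computes anti-image partial correlations from the inverse correlation
#' matrix; KMO is the ratio of summed squared correlations to summed
#' squared correlations plus summed squared partials, and the per-item
#' MSA is the same ratio restricted to each row. For an identity matrix
#' there are no correlations to explain; by convention the indices are
#' returned as 1 with `degenerate = TRUE`.
#'
#' @param R correlation matrix.
#' @return list of class `kmo_result`: `kmo`, `msa` (named per item),
#'   `degenerate`.
#' @export
kmo_msa <- function(R) {
  check_corr_matrix(R)
  p <- ncol(R)
  off <- R[upper.tri(R)]
  if (all(abs(off) < 1e-12))
    return(structure(list(kmo = 1, msa = stats::setNames(rep(1, p), colnames(R)),
                          degenerate = TRUE), class = "kmo_result"))
  Ri <- solve(R)
  s <- 1 / sqrt(diag(Ri))
  Q <- -Ri * outer(s, s)   # anti-image partial correlations
  diag(Q) <- 0
  R0 <- R; diag(R0) <- 0
  kmo <- sum(R0^2) / (sum(R0^2) + sum(Q^2))
  msa <- rowSums(R0^2) / (rowSums(R0^2) + rowSums(Q^2))
  names(msa) <- colnames(R)
  structure(list(kmo = kmo, msa = msa, degenerate = FALSE),
            class = "kmo_result")
}

#' @export
print.kmo_result <- function(x, ...) {
  cat(sprintf("KMO = %.3f; MSA range %.3f-%.3f%s\n", x$kmo, min(x$msa),
              max(x$msa), if (x$degenerate) " (degenerate: identity input)" else ""))
  invisible(x)
}

#' EFA adequacy report
#'
#' Bundles Bartlett's sphericity test with the KMO/MSA coefficients.
#'
#' @inheritParams bartlett_test
#' @return list of class `adequacy_report`.
#' @export
adequacy_report <- function(R, n) {
  b <- bartlett_test(R, n)
  k <- kmo_msa(R)
  structure(c(b[c("chi2", "df", "p_value")],
              list(kmo = k$kmo, msa = k$msa, n = n)),
            class = "adequacy_report")
}
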