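# Maximum-likelihood common-factor extraction and oblique rotation.
#
# The Wishart ML discrepancy is concentrated over the loadings: for a
# candidate uniqueness vector psi the rescaled matrix
# psi^-1/2 R psi^-1/2 is eigendecomposed and the criterion is
# sum_{j>k}(theta_j - log theta_j) - (p - k), minimized over psi by
# L-BFGS-B with its analytic gradient. Loadings then come from the top-k
# eigenpairs at the optimum.

ml_criterion <- function(psi, R, k) {
  sc <- 1 / sqrt(psi)
  e <- eigen(R * outer(sc, sc), symmetric = TRUE, only.values = TRUE)$values
  e <- e[-seq_len(k)]
  sum(e - log(e)) - (ncol(R) - k)
}

ml_gradient <- function(psi, R, k) {
  sc <- 1 / sqrt(psi)
  E <- eigen(R * outer(sc, sc), symmetric = TRUE)
  L <- E$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(E$values[seq_len(k)] - 1, 0)), k)
  L <- L * sqrt(psi)
  g <- L %*% t(L) + diag(psi) - R
  diag(g) / psi^2
}

ml_loadings <- function(psi, R, k) {
  sc <- 1 / sqrt(psi)
  E <- eigen(R * outer(sc, sc), symmetric = TRUE)
  L <- E$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(E$values[seq_len(k)] - 1, 0)), k)
  L * sqrt(psi)
}

# order factors by explained variance, make the dominant loading positive
canonicalize <- function(pattern, Phi = NULL) {
  ss <- colSums(pattern^2)
  ord <- order(ss, decreasing = TRUE)
  pattern <- pattern[, ord, drop = FALSE]
  if (!is.null(Phi)) Phi <- Phi[ord, ord, drop = FALSE]
  sgn <- apply(pattern, 2, function(v) {
    s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s
  })
  pattern <- sweep(pattern, 2, sgn, `*`)
  if (!is.null(Phi)) Phi <- Phi * outer(sgn, sgn)
  list(pattern = pattern, Phi = Phi)
}

#' Maximum-likelihood exploratory factor analysis
#'
#' Fits a k-factor common-factor model to a correlation matrix by
#' maximum likelihood (uniquenesses optimized by L-BFGS-B on the
#' concentrated Wishart criterion, loadings from the eigen-decomposition
#' at the optimum), optionally followed by oblimin rotation. Fit
#' statistics use the Bartlett-corrected chi-square
#' `(n - 1 - (2p+5)/6 - 2k/3) * F_min`, `BIC = chi2 - df * ln(n)` and
#' `RMSEA = sqrt(max(chi2 - df, 0) / (df (n - 1)))`.
#'
#' @param R correlation matrix, or `NULL` if `data` is given.
#' @param n sample size behind `R` (for `data` input the mean pairwise n
#'   is used when `n` is missing).
#' @param k number of factors; `((p-k)^2 - (p+k))/2` must be >= 0.
#' @param data optional raw data (pairwise-complete Pearson correlations
#'   are used).
#' @param rotation `"oblimin"` (default) or `"none"`.
#' @param gamma oblimin gamma (0 = direct quartimin).
#' @param psi_floor lower bound for uniquenesses; a solution at the
#'   floor is a Heywood case and is flagged.
#' @param max_iter optimizer iteration cap.
#' @return object of class `efa_result`: pattern loadings, `Phi`,
#'   uniquenesses, communalities, SS loadings and variance proportions,
#'   `chi2`/`df`/`p_value`/`bic`/`rmsea`, `converged`, `heywood`,
#'   `criterion` (the minimized discrepancy), plus the unrotated
#'   loadings.
#' @export
ml_efa <- function(R = NULL, n = NULL, k, data = NULL,
                   rotation = c("oblimin", "none"), gamma = 0,
                   psi_floor = 0.005, max_iter = 1000) {
  rotation <- match.arg(rotation)
  if (is.null(R)) {
    if (is.null(data)) stop_hz("supply either R or data")
    pc <- pairwise_correlations(data)
    R <- pc$r
    if (is.null(n)) n <- mean(pc$pair_n[upper.tri(pc$pair_n)])
  }
  check_corr_matrix(R)
  p <- ncol(R)
  df <- ((p - k)^2 - (p + k)) / 2
  if (df < 0) stop_hz("k = %d factors over-parameterizes p = %d variables", k, p)
  if (is.null(n)) stop_hz("sample size n is required")

  start <- (1 - 0.5 * k / p) / diag(solve(R))
  start <- pmin(pmax(start, psi_floor), 1)
  opt <- stats::optim(start, ml_criterion, ml_gradient, R = R, k = k,
                      method = "L-BFGS-B", lower = psi_floor, upper = 1,
                      control = list(maxit = max_iter))
  psi <- opt$par
  L <- ml_loadings(psi, R, k)
  heywood <- any(psi <= psi_floor + 1e-8)

  crit <- opt$value
  chi2 <- max((n - 1 - (2 * p + 5) / 6 - 2 * k / 3) * crit, 0)
  p_value <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  bic <- chi2 - df * log(n)
  rmsea <- if (df > 0) sqrt(max(chi2 - df, 0) / (df * (n - 1))) else NA_real_

  unrot <- canonicalize(L)$pattern
  if (rotation == "oblimin" && k >= 2) {
    rot <- oblimin_rotate(unrot, gamma = gamma)
    pattern <- rot$pattern
    Phi <- rot$Phi
    rot_converged <- rot$converged
  } else {
    pattern <- unrot
    Phi <- diag(k)
    rot_converged <- TRUE
  }
  dimnames(pattern) <- list(colnames(R), paste0("F", seq_len(k)))
  dimnames(Phi) <- list(colnames(pattern), colnames(pattern))
  h2 <- rowSums((pattern %*% Phi) * pattern)
  ss <- colSums(pattern^2)

  structure(list(
    k = k, pattern_loadings = pattern, Phi = Phi,
    uniquenesses = stats::setNames(psi, colnames(R)),
    communalities = stats::setNames(h2, colnames(R)),
    ss_loadings = ss, proportion_variance = ss / p,
    unrotated_loadings = `dimnames<-`(unrot, dimnames(pattern)),
    ss_unrotated = colSums(unrot^2),
    chi2 = chi2, df = df, p_value = p_value, bic = bic, rmsea = rmsea,
    criterion = crit, n = n, rotation = rotation, gamma = gamma,
    converged = opt$convergence == 0 && rot_converged,
    heywood = heywood
  ), class = "efa_result")
}

#' @export
print.efa_result <- function(x, digits = 2, ...) {
  cat(sprintf("ML EFA, %d factor(s), %s rotation (n = %.0f)\n",
              x$k, x$rotation, x$n))
  cat("Pattern loadings:\n")
  print(round(x$pattern_loadings, digits))
  if (x$k > 1) {
    cat("Factor correlations (Phi):\n")
    print(round(x$Phi, digits))
  }
  cat(sprintf("chi2(%d) = %.2f, p = %.3g, BIC = %.1f, RMSEA = %.3f%s%s\n",
              x$df, x$chi2, x$p_value, x$bic, x$rmsea,
              if (x$heywood) " [Heywood]" else "",
              if (!x$converged) " [NOT converged]" else ""))
  invisible(x)
}

#' Oblimin (direct quartimin) rotation by gradient projection
#'
#' Oblique rotation of an unrotated loading matrix minimizing the
#' oblimin criterion (`gamma = 0` gives direct quartimin) via the
#' gradient-projection algorithm. Communalities are invariant:
#' `diag(P Phi P')` equals the unrotated `diag(A A')` to numerical
#' precision.
#'
#' @param loadings p x k unrotated loading matrix (k >= 2; a single
#'   factor is returned unchanged).
#' @param gamma oblimin weight, default 0.
#' @param max_iter,tol gradient-projection iteration cap and gradient
#'   tolerance.
#' @return list: `pattern`, `Phi`, `converged`, `iterations`. Factors
#'   are ordered by explained variance with dominant loadings positive.
#' @export
oblimin_rotate <- function(loadings, gamma = 0, max_iter = 1000, tol = 1e-6) {
  A <- as.matrix(loadings)
  k <- ncol(A)
  if (k < 2)
    return(list(pattern = A, Phi = diag(k), converged = TRUE, iterations = 0L))
  p <- nrow(A)
  N <- matrix(1, k, k) - diag(k)
  vg <- function(L) {
    X <- L^2 %*% N
    if (gamma != 0) X <- (diag(p) - gamma * matrix(1 / p, p, p)) %*% X
    list(f = sum(L^2 * X) / 4, G = L * X)
  }
  Tm <- diag(k)
  Ti <- solve(Tm)
  L <- A %*% t(Ti)
  q <- vg(L)
  f <- q$f
  G <- -t(t(L) %*% q$G %*% Ti)
  al <- 1
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    Gp <- G - Tm %*% diag(colSums(Tm * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < tol) { converged <- TRUE; break }
    al <- 2 * al
    for (i in 1:20) {
      X <- Tm - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      q <- vg(L)
      if (q$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tm <- Tt
    f <- q$f
    G <- -t(t(L) %*% q$G %*% Ti)
  }
  Phi <- t(Tm) %*% Tm
  out <- canonicalize(L, Phi)
  list(pattern = out$pattern, Phi = out$Phi, converged = converged,
       iterations = iter)
}

#' Higher-order factor from first-order factor correlations
#'
#' Extracts a single general factor from the k x k factor correlation
#' matrix Phi. For k = 2 the model is just-identified and both
#' g-loadings equal `sqrt(|Phi[1,2]|)` (closed form); for k > 2 a
#' one-factor ML solution is fitted to Phi. The leading eigenvalue of
#' Phi and its share of the total variance k are reported.
#'
#' @param Phi factor correlation matrix (k >= 2).
#' @return list of class `higher_order_result`: `g_loadings`,
#'   `g_eigenvalue` (leading eigenvalue of Phi),
#'   `proportion_variance_of_Phi` (`g_eigenvalue / k`), `degenerate`
#'   (at-bound solution).
#' @export
higher_order_factor <- function(Phi) {
  check_corr_matrix(Phi, require_pd = FALSE)
  k <- ncol(Phi)
  if (k < 2) stop_hz("higher-order extraction needs k >= 2 first-order factors")
  ev <- eigen(Phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop_hz("Phi is not positive semi-definite")
  if (k == 2) {
    r <- Phi[1, 2]
    g <- sqrt(abs(r)) * c(1, sign(r))
    degenerate <- abs(r) >= 1 - 1e-8
  } else {
    fit <- ml_efa(R = Phi, n = 1000, k = 1, rotation = "none")
    g <- drop(fit$pattern_loadings)
    degenerate <- fit$heywood
  }
  names(g) <- colnames(Phi) %||% paste0("F", seq_len(k))
  structure(list(g_loadings = g, g_eigenvalue = max(ev),
                 proportion_variance_of_Phi = max(ev) / k,
                 degenerate = degenerate),
            class = "higher_order_result")
}
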