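#' Round half away from zero
#'
#' Report tables mirror the source instrument's convention of rounding
#' half-up (0.275 -> 0.28), unlike [base::round()]'s round-half-even.
#' Machine-readable outputs always keep full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# three-valued helpers: R logical NA carries "indeterminate"
tv_chr <- function(x) ifelse(is.na(x), "indeterminate", ifelse(x, "true", "false"))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hz <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# symmetric positive-definiteness check used by the matrix-input EFA ops
check_corr_matrix <- function(R, require_pd = TRUE) {
  if (!is.matrix(R) || nrow(R) != ncol(R))
    stop_hz("correlation matrix must be square")
  if (max(abs(R - t(R))) > 1e-8)
    stop_hz("correlation matrix must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8)
    stop_hz("correlation matrix must have unit diagonal")
  if (require_pd) {
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop_hz("correlation matrix is not positive definite (min eigenvalue %.3g)",
              min(ev))
  }
  invisible(TRUE)
}
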