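#' @useDynLib bmsdesign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm integrate optimize pnorm rnorm runif setNames var
#' @importFrom utils head tail
NULL

LOG2 <- log(2)

#' Shannon entropy of a probability vector, in bits
#' @param p nonnegative vector summing to one.
#' @return entropy in bits.
#' @keywords internal
#' @noRd
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

## log-determinant of a symmetric positive-definite matrix via Cholesky
logdet_pd <- function(M) {
  2 * sum(log(diag(chol(M))))
}

is_symmetric_tol <- function(M, tol = 1e-10) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) return(FALSE)
  if (nrow(M) == 0L) return(TRUE)
  max(abs(M - t(M))) <= tol * max(1, max(abs(M)))
}

#' Symmetrize a covariance and, if needed, add a small ridge
#'
#' Long time series make Laplace predictive covariances ill-conditioned; this
#' repairs indefiniteness by symmetrizing and then adding a scaled-identity
#' ridge (a multiple of `trace/n`), warning when it does so.
#'
#' @param M square matrix.
#' @param ridge relative ridge added per repair pass.
#' @param max_tries maximum number of escalating passes.
#' @return symmetric positive-definite matrix.
#' @keywords internal
#' @noRd
repair_pd <- function(M, ridge = 1e-10, max_tries = 6L) {
  M <- (M + t(M)) / 2
  ok <- !inherits(try(chol(M), silent = TRUE), "try-error")
  if (ok) return(M)
  n <- nrow(M)
  base <- max(sum(diag(M)) / n, .Machine$double.eps)
  r <- ridge
  for (i in seq_len(max_tries)) {
    Mj <- M + diag(r * base, n)
    if (!inherits(try(chol(Mj), silent = TRUE), "try-error")) {
      warning(sprintf("covariance repaired to positive-definiteness (ridge %g)",
                      r * base), call. = FALSE)
      return(Mj)
    }
    r <- r * 100
  }
  stop("degenerate covariance: could not be repaired to positive-definiteness",
       call. = FALSE)
}

## validate a probability vector
check_priors <- function(p, n = NULL, tol = 1e-12, what = "model_priors") {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
    stop(sprintf("%s must be a finite nonnegative numeric vector", what),
         call. = FALSE)
  if (!is.null(n) && length(p) != n)
    stop(sprintf("%s has length %d, expected %d", what, length(p), n),
         call. = FALSE)
  if (abs(sum(p) - 1) > max(tol, 1e-12))
    stop(sprintf("%s must sum to 1 (got %.15g)", what, sum(p)), call. = FALSE)
  p
}

## central finite-difference Jacobian with per-parameter step
## max(h, h * |theta_i|)
fd_jacobian <- function(f, theta, h = 1e-4) {
  f0 <- f(theta)
  J <- matrix(0, length(f0), length(theta))
  for (i in seq_along(theta)) {
    hi <- max(h, h * abs(theta[i]))
    tp <- theta; tp[i] <- tp[i] + hi
    tm <- theta; tm[i] <- tm[i] - hi
    fp <- f(tp); fm <- f(tm)
    if (any(!is.finite(fp)) || any(!is.finite(fm)))
      stop(sprintf("non-finite observation mapping output perturbing parameter %d",
                   i), call. = FALSE)
    J[, i] <- (fp - fm) / (2 * hi)
  }
  J
}

## forward-difference Jacobian reusing the already-computed f(theta); cheaper
## (p+1 evaluations) and accurate enough for Gauss-Newton ascent
fd_jacobian_fwd <- function(f, theta, f0, h = 1e-4) {
  J <- matrix(0, length(f0), length(theta))
  for (i in seq_along(theta)) {
    hi <- max(h, h * abs(theta[i]))
    tp <- theta; tp[i] <- tp[i] + hi
    fp <- f(tp)
    if (any(!is.finite(fp)))
      stop(sprintf("non-finite observation mapping output perturbing parameter %d",
                   i), call. = FALSE)
    J[, i] <- (fp - f0) / hi
  }
  J
}

## draw from N(mean, cov); thin wrapper kept internal so callers share one path
rmvn <- function(n, mean, cov) {
  if (length(mean) == 1L) {
    matrix(rnorm(n, mean, sqrt(drop(cov))), ncol = 1L)
  } else {
    matrix(MASS::mvrnorm(n, mu = mean, Sigma = cov), nrow = n,
           ncol = length(mean))
  }
}

## Gaussian log-density with precomputed Cholesky factor
dmvn_log <- function(Y, mean, cholQ) {
  Y <- if (is.matrix(Y)) Y else matrix(Y, ncol = length(mean))
  d <- ncol(Y)
  z <- backsolve(cholQ, t(Y) - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(cholQ))) - 0.5 * colSums(z^2)
}
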