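## General-linear-model special case: classical C-optimality efficiency, the
## GLM Laplace-Chernoff risk, and their frequentist-limit equivalence.

#' GLM design for a single-contrast test
#'
#' A general linear model `y = X theta + e` with i.i.d. Gaussian parameter
#' priors `N(0, v I)` and noise variance `sigma^2`, set up to test whether
#' one contrast of parameters is zero. A general contrast vector is handled
#' by an orthonormal rotation of the design matrix that turns the contrast
#' into a single column, after which `contrast_index` designates that column.
#'
#' @param X n-by-p design matrix (finite, `n >= p >= 1`).
#' @param noise_var noise variance `sigma^2 > 0`.
#' @param prior_var prior variance `v > 0` of each parameter.
#' @param contrast either a column index in `1..p` or a length-p contrast
#'   vector (rotated into column 1).
#' @return an object of class `glm_design`.
#' @export
glm_design <- function(X, noise_var, prior_var, contrast = 1L) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X must be finite", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (n < p || p < 1L) stop("need n >= p >= 1", call. = FALSE)
  if (!is.numeric(noise_var) || noise_var <= 0)
    stop("noise_var must be > 0", call. = FALSE)
  if (!is.numeric(prior_var) || prior_var <= 0)
    stop("prior_var must be > 0", call. = FALSE)
  if (length(contrast) == 1L) {
    i <- as.integer(contrast)
    if (i < 1L || i > p) stop("contrast_index out of range", call. = FALSE)
  } else {
    if (length(contrast) != p || all(contrast == 0))
      stop("contrast vector must be length p and nonzero", call. = FALSE)
    ## orthonormal basis whose first vector is the normalized contrast;
    ## an orthonormal rotation leaves the isotropic prior invariant
    Qb <- qr.Q(qr(cbind(contrast / sqrt(sum(contrast^2)), diag(p))))[, 1:p]
    if (sum(Qb[, 1] * contrast) < 0) Qb[, 1] <- -Qb[, 1]
    X <- X %*% Qb
    i <- 1L
  }
  structure(list(X = X, noise_var = noise_var, prior_var = prior_var,
                 contrast_index = i), class = "glm_design")
}

## orthogonal projector residual-forming matrix of the reduced design
residual_projector <- function(Xr, n) {
  if (ncol(Xr) == 0L) return(diag(n))
  sv <- svd(Xr)
  keep <- sv$d > max(dim(Xr)) * .Machine$double.eps * sv$d[1]
  U <- sv$u[, keep, drop = FALSE]
  diag(n) - tcrossprod(U)
}

#' Classical (C-optimality) design efficiency of a contrast
#'
#' Efficiency of testing that the designated parameter is zero: the inverse
#' of the variance of its maximum-likelihood contrast estimate, i.e.
#' `x_i' (I - P) x_i / sigma^2` where `P` projects onto the span of the
#' remaining columns. Exact collinearity of the tested column with the rest
#' yields efficiency 0 (with a warning).
#'
#' @param glm a [glm_design()].
#' @return nonnegative efficiency scalar.
#' @export
classical_efficiency <- function(glm) {
  stopifnot(inherits(glm, "glm_design"))
  i <- glm$contrast_index
  xi <- glm$X[, i]
  R <- residual_projector(glm$X[, -i, drop = FALSE], nrow(glm$X))
  e <- drop(crossprod(xi, R %*% xi)) / glm$noise_var
  if (e < sum(xi^2) / glm$noise_var * 1e-12) {
    warning("tested column is (numerically) collinear with the remaining columns: efficiency 0",
            call. = FALSE)
    return(0)
  }
  e
}

#' Laplace-Chernoff risk of a GLM contrast test
#'
#' Risk of the Bayesian analogue of the classical test: comparing the model
#' with the full design matrix `X` against the model with the tested column
#' removed, under i.i.d. `N(0, v)` parameter priors and flat model priors.
#' The closed form is `b_LC = 1 - (1/2) log2(1 + s/2) + (1/4) log2(1 + s)`
#' with `s = v x_i' (sigma^2 I + v X_r X_r')^{-1} x_i` (`X_r` the reduced
#' design); the `method = "generic"` path instead builds both linear models
#' explicitly and calls [laplace_chernoff_risk()], and agrees with the closed
#' form to numerical precision because the Taylor expansion is exact for
#' linear mappings. Risk attains its maximum (1 bit, indistinguishable
#' models) as `v` tends to 0.
#'
#' @param glm a [glm_design()].
#' @param method `"closed-form"` (default) or `"generic"`.
#' @return scalar risk in bits.
#' @export
glm_risk <- function(glm, method = c("closed-form", "generic")) {
  stopifnot(inherits(glm, "glm_design"))
  method <- match.arg(method)
  X <- glm$X; n <- nrow(X); i <- glm$contrast_index
  v <- glm$prior_var; s2 <- glm$noise_var
  if (method == "closed-form") {
    Xr <- X[, -i, drop = FALSE]
    xi <- X[, i]
    Q2 <- diag(s2, n) + v * tcrossprod(Xr)
    s <- v * drop(crossprod(xi, solve(Q2, xi)))
    1 - 0.5 * log2(1 + s / 2) + 0.25 * log2(1 + s)
  } else {
    full <- ng_model("full", function(th, u) drop(X %*% th),
                     prior_mean = rep(0, ncol(X)), prior_cov = v,
                     noise_cov = s2, n_y = n)
    red <- ng_model("reduced",
                    function(th, u) drop(X[, -i, drop = FALSE] %*% th),
                    prior_mean = rep(0, ncol(X) - 1L), prior_cov = v,
                    noise_cov = s2, n_y = n)
    rep_ <- suppressWarnings(
      laplace_chernoff_risk(model_set(list(full, red)), design = NULL,
                            noise_mode = "fixed"))
    rep_$laplace_chernoff_risk
  }
}

#' Agreement of Bayesian risk and classical efficiency rankings
#'
#' For each prior variance in `v_grid`, ranks the candidate designs by
#' [glm_risk()] (ascending: best first) and by [classical_efficiency()]
#' (descending: best first). At the frequentist limit (the largest `v`), the
#' minimum-risk design coincides with the maximum-efficiency design; at
#' small `v` the rankings may diverge, which is reported, not an error.
#'
#' @param designs list of [glm_design()] objects sharing `contrast_index` and
#'   `noise_var` (each design's own `prior_var` is ignored).
#' @param v_grid increasing vector of prior variances; the default realizes
#'   the non-informative limit numerically as `1e6 * sigma^2`.
#' @return list with `efficiency`, per-`v` `risk` matrix, per-`v` rankings,
#'   `agree` (per-`v` flag: argmin risk equals argmax efficiency) and
#'   `limit_agrees` for the largest `v`.
#' @export
frequentist_limit_ranking <- function(designs, v_grid = NULL) {
  if (!is.list(designs) || length(designs) < 2L)
    stop("need at least 2 candidate designs", call. = FALSE)
  stopifnot(all(vapply(designs, inherits, logical(1), "glm_design")))
  s2 <- unique(vapply(designs, function(d) d$noise_var, numeric(1)))
  if (length(s2) != 1L)
    stop("designs must share one noise variance", call. = FALSE)
  if (is.null(v_grid)) v_grid <- c(1, 100, 1e6) * s2
  v_grid <- sort(v_grid)
  eff <- vapply(designs, classical_efficiency, numeric(1))
  risk <- sapply(v_grid, function(v) {
    vapply(designs, function(d) {
      d$prior_var <- v
      glm_risk(d)
    }, numeric(1))
  })
  risk <- matrix(risk, nrow = length(designs),
                 dimnames = list(NULL, paste0("v=", signif(v_grid, 3))))
  rank_risk <- apply(risk, 2L, order)           # ascending risk
  rank_eff <- order(eff, decreasing = TRUE)     # descending efficiency
  agree <- apply(risk, 2L, which.min) == which.max(eff)
  list(efficiency = eff, v_grid = v_grid, risk = risk,
       risk_ranking = rank_risk, efficiency_ranking = rank_eff,
       agree = agree, limit_agrees = unname(tail(agree, 1L)))
}
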