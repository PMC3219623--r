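## Nonlinear Gaussian generative models and Laplace approximation of their
## prior predictive densities.

#' Nonlinear Gaussian generative model
#'
#' Defines a generative model of the form `y = g(theta, u) + e`, where `g` is a
#' deterministic observation mapping of parameters `theta` under an
#' experimental design `u`, `theta` carries a Gaussian prior `N(eta,
#' Sigma_theta)`, and the residuals `e` are zero-mean Gaussian with covariance
#' `Sigma_eps` (or, by default, an isotropic covariance set by the expected
#' residual precision of a Gamma hyperprior).
#'
#' @param name identifier used in error messages and reports.
#' @param observation_mapping `function(theta, design)` returning a numeric
#'   data vector; must be deterministic.
#' @param prior_mean prior mean `eta` of the parameters.
#' @param prior_cov prior covariance `Sigma_theta`: a symmetric
#'   positive-semidefinite matrix, or a scalar/vector shorthand for a diagonal.
#' @param noise_cov fixed residual covariance `Sigma_eps`: matrix, or scalar
#'   variance shorthand for `variance * I`. May be `NULL` when the
#'   expected-precision noise mode is used throughout.
#' @param noise_precision_prior `c(shape, scale)` of a Gamma density over the
#'   residual precision; its mean `shape * scale` is the expected precision.
#' @param n_y declared data dimension, or `NULL` if it depends on the design.
#' @param design optional design used to validate the mapping at the prior
#'   mean.
#' @return an object of class `ng_model`.
#' @seealso [laplace_predictive()], [model_set()]
#' @export
ng_model <- function(name, observation_mapping, prior_mean, prior_cov,
                     noise_cov = NULL,
                     noise_precision_prior = c(shape = 1, scale = 1),
                     n_y = NULL, design = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(observation_mapping))
  prior_mean <- as.numeric(prior_mean)
  p <- length(prior_mean)
  if (!is.matrix(prior_cov)) {
    prior_cov <- diag(rep_len(as.numeric(prior_cov), p), p)
  }
  if (!is_symmetric_tol(prior_cov))
    stop(sprintf("model '%s': prior_cov must be symmetric (tol 1e-10)", name),
         call. = FALSE)
  if (nrow(prior_cov) != p)
    stop(sprintf("model '%s': prior_cov dimension %d does not match prior_mean length %d",
                 name, nrow(prior_cov), p), call. = FALSE)
  if (p > 0 && min(eigen(prior_cov, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-10 * max(1, max(abs(prior_cov))))
    stop(sprintf("model '%s': prior_cov is not positive-semidefinite", name),
         call. = FALSE)
  if (!is.null(noise_cov) && !is.matrix(noise_cov) && length(noise_cov) == 1L) {
    if (noise_cov <= 0)
      stop(sprintf("model '%s': scalar noise variance must be > 0", name),
           call. = FALSE)
  } else if (is.matrix(noise_cov)) {
    if (!is_symmetric_tol(noise_cov))
      stop(sprintf("model '%s': noise_cov must be symmetric (tol 1e-10)", name),
           call. = FALSE)
    if (min(eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop(sprintf("model '%s': noise_cov must be positive-definite", name),
           call. = FALSE)
  }
  npp <- as.numeric(noise_precision_prior)
  if (length(npp) != 2L || any(!is.finite(npp)) || any(npp <= 0))
    stop(sprintf("model '%s': Gamma hyperprior needs shape > 0 and scale > 0",
                 name), call. = FALSE)
  m <- structure(
    list(name = name, observation_mapping = observation_mapping,
         prior_mean = prior_mean, prior_cov = prior_cov,
         noise_cov = noise_cov,
         noise_precision_prior = c(shape = npp[1], scale = npp[2]),
         n_y = n_y),
    class = "ng_model")
  if (!is.null(design)) {
    y0 <- observation_mapping(prior_mean, design)
    if (any(!is.finite(y0)))
      stop(sprintf("model '%s': observation mapping at the prior mean is not finite",
                   name), call. = FALSE)
    if (!is.null(n_y) && length(y0) != n_y)
      stop(sprintf("model '%s': mapping returned length %d, declared n_y = %d",
                   name, length(y0), n_y), call. = FALSE)
    if (is.null(n_y)) m$n_y <- length(y0)
  }
  m
}

#' @export
print.ng_model <- function(x, ...) {
  cat(sprintf("<ng_model '%s': %d parameter(s), n_y = %s>\n", x$name,
              length(x$prior_mean), ifelse(is.null(x$n_y), "design-dependent",
                                           x$n_y)))
  invisible(x)
}

#' Comparison set of generative models
#'
#' Bundles candidate models with their prior probabilities and an optional
#' partition into model families.
#'
#' @param models list of [ng_model()] objects.
#' @param model_priors prior probability of each model; defaults to uniform.
#' @param family_labels optional vector (one entry per model) naming the
#'   family each model belongs to.
#' @return an object of class `model_set`.
#' @examples
#' m <- function(nm, b) ng_model(nm, function(th, u) b * th, 0, 1,
#'                               noise_cov = 1)
#' ms <- model_set(list(m("m1", 1), m("m2", 2)))
#' ms$model_priors
#' @export
model_set <- function(models, model_priors = NULL, family_labels = NULL) {
  if (!is.list(models) || length(models) < 2L)
    stop("a model set needs at least 2 models", call. = FALSE)
  bad <- which(!vapply(models, inherits, logical(1), "ng_model"))
  if (length(bad))
    stop(sprintf("models[[%d]] is not an ng_model", bad[1]), call. = FALSE)
  M <- length(models)
  if (is.null(model_priors)) model_priors <- rep(1 / M, M)
  model_priors <- check_priors(model_priors, M)
  nys <- unique(unlist(lapply(models, function(m) m$n_y)))
  if (length(nys) > 1L)
    stop(sprintf("models disagree on data dimension n_y: %s (model '%s' differs)",
                 paste(nys, collapse = ", "),
                 models[[which(vapply(models, function(m)
                   !is.null(m$n_y) && m$n_y != nys[1], logical(1)))[1]]]$name),
         call. = FALSE)
  if (!is.null(family_labels)) {
    if (length(family_labels) != M)
      stop("family_labels must assign exactly one label per model",
           call. = FALSE)
    if (any(is.na(family_labels)))
      stop("family_labels must not contain NA", call. = FALSE)
    if (length(unique(family_labels)) < 1L || any(table(family_labels) < 1L))
      stop("every family must be non-empty", call. = FALSE)
  }
  nm <- vapply(models, function(m) m$name, character(1))
  structure(list(models = models, model_priors = model_priors,
                 family_labels = family_labels, names = nm),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("<model_set: %d models (%s)>\n", length(x$models),
              paste(x$names, collapse = ", ")))
  if (!is.null(x$family_labels))
    cat("  families:", paste(unique(x$family_labels), collapse = ", "), "\n")
  invisible(x)
}

#' Build a validated model set from model definitions
#'
#' Convenience wrapper accepting either ready-made [ng_model()] objects or
#' definition lists of arguments to [ng_model()].
#'
#' @param specs non-empty list of `ng_model` objects or argument lists.
#' @param priors optional model prior probabilities (default uniform).
#' @param families optional family labels, one per model.
#' @return a [model_set()].
#' @export
build_model_set <- function(specs, priors = NULL, families = NULL) {
  if (!length(specs)) stop("specs must be non-empty", call. = FALSE)
  models <- lapply(specs, function(s) {
    if (inherits(s, "ng_model")) s else do.call(ng_model, s)
  })
  model_set(models, model_priors = priors, family_labels = families)
}

#' Gaussian summary of a predictive density
#'
#' First two moments of a (Laplace-approximated) prior predictive density over
#' data space.
#'
#' @param mean data-space mean vector.
#' @param cov symmetric covariance matrix (scalar shorthand allowed in 1-D).
#' @return an object of class `gaussian_predictive`.
#' @export
gaussian_predictive <- function(mean, cov) {
  mean <- as.numeric(mean)
  if (!is.matrix(cov)) cov <- matrix(as.numeric(cov), 1L, 1L)
  if (!is_symmetric_tol(cov))
    stop("predictive cov must be symmetric (tol 1e-10)", call. = FALSE)
  if (length(mean) != nrow(cov))
    stop(sprintf("predictive mean length %d does not match cov dimension %d",
                 length(mean), nrow(cov)), call. = FALSE)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(1, max(abs(cov))))
    stop("predictive cov has negative eigenvalues beyond tolerance",
         call. = FALSE)
  structure(list(mean = mean, cov = cov), class = "gaussian_predictive")
}

#' @export
print.gaussian_predictive <- function(x, ...) {
  cat(sprintf("<gaussian_predictive: dimension %d>\n", length(x$mean)))
  invisible(x)
}

## residual covariance implied by the model under a noise mode
noise_cov_of <- function(model, n, noise_mode) {
  if (noise_mode == "fixed") {
    if (is.null(model$noise_cov))
      stop(sprintf("model '%s' has no fixed noise covariance", model$name),
           call. = FALSE)
    if (is.matrix(model$noise_cov)) {
      if (nrow(model$noise_cov) != n)
        stop(sprintf("model '%s': noise_cov dimension %d does not match n_y = %d",
                     model$name, nrow(model$noise_cov), n), call. = FALSE)
      model$noise_cov
    } else diag(drop(model$noise_cov), n)
  } else {
    lam <- model$noise_precision_prior[["shape"]] *
      model$noise_precision_prior[["scale"]]
    diag(1 / lam, n)
  }
}

#' Laplace approximation of a model's prior predictive density
#'
#' Propagates the parameter prior through a first-order Taylor expansion of
#' the observation mapping around the prior mean: the predictive mean is
#' `g(eta, u)` and the predictive covariance is `J Sigma_theta J' +
#' Sigma_eps`, with `J` the Jacobian of the mapping at the prior mean. For an
#' affine mapping this is the exact Gaussian predictive.
#'
#' @param model an [ng_model()].
#' @param design design object passed through to the observation mapping.
#' @param jacobian_method only `"finite-difference"` (central differences with
#'   per-parameter step `max(1e-4, 1e-4 |eta_i|)`) is available.
#' @param noise_mode `"expected-precision"` uses `Sigma_eps = I / (shape *
#'   scale)` from the Gamma hyperprior (the default, since the error-rate
#'   bounds are conditional on the expected noise precision);
#'   `"fixed"` uses the model's `noise_cov`.
#' @return a [gaussian_predictive()].
#' @export
laplace_predictive <- function(model, design = NULL,
                               jacobian_method = c("finite-difference",
                                                   "sensitivity"),
                               noise_mode = c("expected-precision", "fixed")) {
  stopifnot(inherits(model, "ng_model"))
  jacobian_method <- match.arg(jacobian_method)
  if (jacobian_method == "sensitivity")
    stop("sensitivity-equation Jacobians are not implemented; use \"finite-difference\"",
         call. = FALSE)
  noise_mode <- match.arg(noise_mode)
  g <- function(th) model$observation_mapping(th, design)
  mu <- g(model$prior_mean)
  if (any(!is.finite(mu)))
    stop(sprintf("model '%s': non-finite mapping output at the prior mean (first bad index %d)",
                 model$name, which(!is.finite(mu))[1]), call. = FALSE)
  n <- length(mu)
  Se <- noise_cov_of(model, n, noise_mode)
  if (length(model$prior_mean) == 0L || all(model$prior_cov == 0)) {
    Q <- Se
  } else {
    J <- fd_jacobian(g, model$prior_mean)
    Q <- J %*% model$prior_cov %*% t(J) + Se
  }
  Q <- repair_pd(Q)
  gaussian_predictive(mu, Q)
}
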