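## Information-theoretic machinery: Jensen-Shannon divergence, Chernoff-type
## bounds on the model selection error rate, the Laplace-Chernoff risk, the
## family-level extension, and exact low-dimensional oracles.

#' Kullback-Leibler divergence between two Gaussian densities
#'
#' @param p,q [gaussian_predictive()] objects of the same dimension; `q$cov`
#'   must be invertible.
#' @param units `"bits"` (default) or `"nats"`.
#' @return nonnegative scalar divergence `KL(p || q)`.
#' @export
kl_gaussian <- function(p, q, units = c("bits", "nats")) {
  units <- match.arg(units)
  stopifnot(inherits(p, "gaussian_predictive"),
            inherits(q, "gaussian_predictive"))
  d <- length(p$mean)
  if (length(q$mean) != d)
    stop(sprintf("dimension mismatch: p is %d-dimensional, q is %d-dimensional",
                 d, length(q$mean)), call. = FALSE)
  cq <- try(chol(q$cov), silent = TRUE)
  if (inherits(cq, "try-error")) {
    stop(sprintf("q$cov is singular or indefinite (reciprocal condition number %.3g)",
                 rcond(q$cov)), call. = FALSE)
  }
  iq <- chol2inv(cq)
  dm <- q$mean - p$mean
  kl_nats <- 0.5 * (sum(iq * p$cov) + sum(dm * (iq %*% dm)) - d +
                      2 * sum(log(diag(cq))) - logdet_pd(p$cov))
  kl_nats <- max(kl_nats, 0)
  if (units == "bits") kl_nats / LOG2 else kl_nats
}

## moment-matched Gaussian collapse of a mixture of Gaussian predictives
mix_moments <- function(predictives, priors) {
  mu <- Reduce(`+`, Map(function(pd, w) w * pd$mean, predictives,
                        as.list(priors)))
  Q <- Reduce(`+`, Map(function(pd, w) {
    d <- pd$mean - mu
    w * (pd$cov + tcrossprod(d))
  }, predictives, as.list(priors)))
  list(mean = mu, cov = (Q + t(Q)) / 2)
}

check_predictives <- function(predictives) {
  if (!is.list(predictives) || length(predictives) < 2L)
    stop("need at least 2 predictive densities", call. = FALSE)
  ok <- vapply(predictives, inherits, logical(1), "gaussian_predictive")
  if (!all(ok))
    stop("predictives must be gaussian_predictive objects", call. = FALSE)
  d <- unique(vapply(predictives, function(p) length(p$mean), integer(1)))
  if (length(d) != 1L)
    stop("predictive densities must share one data dimension", call. = FALSE)
  d
}

## mixture log-density over rows of Y
mixture_logdens <- function(Y, predictives, priors) {
  L <- vapply(seq_along(predictives), function(m) {
    dmvn_log(Y, predictives[[m]]$mean, chol(predictives[[m]]$cov)) +
      log(priors[m])
  }, numeric(if (is.matrix(Y)) nrow(Y) else 1L))
  L <- if (is.matrix(L)) L else matrix(L, nrow = 1L)
  mx <- apply(L, 1L, max)
  mx + log(rowSums(exp(L - mx)))
}

#' Jensen-Shannon divergence of a set of predictive densities
#'
#' Entropy of the prior-weighted mixture minus the prior-weighted average
#' entropy of the component densities. Three evaluation methods are
#' available: `"laplace"` replaces the mixture entropy by the entropy of its
#' moment-matched Gaussian (closed form, any dimension); `"quadrature"`
#' integrates the mixture entropy numerically (1-D only); `"monte-carlo"`
#' estimates it by stratified sampling from the mixture (the estimate carries
#' its standard error as attribute `"se"`).
#'
#' @param predictives list of [gaussian_predictive()] objects (at least 2).
#' @param model_priors prior model probabilities (default uniform).
#' @param method `"laplace"`, `"quadrature"` or `"monte-carlo"`.
#' @param mc_samples total Monte-Carlo sample size.
#' @param seed mandatory seed for the Monte-Carlo method.
#' @param units `"bits"` (default) or `"nats"`.
#' @return scalar divergence; zero iff all densities are equal, and at most
#'   the entropy of `model_priors`(1 bit for two equiprobable models) for the
#'   exact methods.
#' @export
jensen_shannon <- function(predictives, model_priors = NULL,
                           method = c("laplace", "quadrature", "monte-carlo"),
                           mc_samples = 1e5, seed = NULL,
                           units = c("bits", "nats")) {
  method <- match.arg(method)
  units <- match.arg(units)
  d <- check_predictives(predictives)
  M <- length(predictives)
  if (is.null(model_priors)) model_priors <- rep(1 / M, M)
  model_priors <- check_priors(model_priors, M)

  ## average component entropy, nats
  h_avg <- sum(vapply(seq_len(M), function(m) {
    model_priors[m] *
      0.5 * (d * (1 + log(2 * pi)) + logdet_pd(predictives[[m]]$cov))
  }, numeric(1)))

  if (method == "laplace") {
    mm <- mix_moments(predictives, model_priors)
    h_mix <- 0.5 * (d * (1 + log(2 * pi)) + logdet_pd(repair_pd(mm$cov)))
    js <- max(h_mix - h_avg, 0)
  } else if (method == "quadrature") {
    if (d != 1L)
      stop("quadrature is only supported for univariate densities",
           call. = FALSE)
    ## integrate the mixture entropy piecewise around each component so that
    ## widely separated components are not missed
    sds <- vapply(predictives, function(p) sqrt(p$cov[1, 1]), numeric(1))
    mus <- vapply(predictives, function(p) p$mean, numeric(1))
    lo <- mus - 12 * sds; hi <- mus + 12 * sds
    brk <- sort(unique(c(lo, hi)))
    f <- function(y) {
      ld <- mixture_logdens(matrix(y, ncol = 1), predictives, model_priors)
      ifelse(is.finite(ld), -exp(ld) * ld, 0)
    }
    h_mix <- sum(vapply(seq_len(length(brk) - 1L), function(i) {
      integrate(f, brk[i], brk[i + 1], subdivisions = 400L,
                rel.tol = 1e-10, abs.tol = 1e-12)$value
    }, numeric(1)))
    js <- h_mix - h_avg
  } else {
    if (is.null(seed)) stop("monte-carlo JSD requires a seed", call. = FALSE)
    ## stratified: D_JS = sum_m p_m E_{p_m}[ log p_m(y) - log pbar(y) ]
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    est <- var_s <- 0
    for (m in seq_len(M)) {
      nm <- max(2L, round(mc_samples * model_priors[m]))
      Y <- rmvn(nm, predictives[[m]]$mean, predictives[[m]]$cov)
      lp <- dmvn_log(Y, predictives[[m]]$mean, chol(predictives[[m]]$cov))
      lmix <- mixture_logdens(Y, predictives, model_priors)
      r <- lp - lmix
      est <- est + model_priors[m] * mean(r)
      var_s <- var_s + model_priors[m]^2 * var(r) / nm
    }
    js <- est
    attr(js, "se") <- sqrt(var_s) / if (units == "bits") LOG2 else 1
  }
  val <- if (units == "bits") js / LOG2 else js
  if (method == "monte-carlo") attr(val, "se") <- attr(js, "se")
  val
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Chernoff-type bounds on the model selection error rate
#'
#' Lower and upper bounds on the selection error rate as a function of the
#' Jensen-Shannon divergence `D_JS` between the models' predictive densities:
#' `(H - D_JS)^2 / (4 (M - 1)) <= p(e|u) <= (H - D_JS) / 2`, where `H` is the
#' Shannon entropy of the model priors and `M` the number of models (all in
#' bits). Both bounds decrease monotonically in `D_JS`; for two equiprobable
#' models the upper bound tends to 0.5 as `D_JS` tends to 0 and both bounds
#' vanish at `D_JS = 1` bit.
#'
#' @param jsd Jensen-Shannon divergence in bits.
#' @param model_priors prior model probabilities.
#' @return named vector `c(lower_bound, upper_bound)`.
#' @export
chernoff_bounds <- function(jsd, model_priors) {
  model_priors <- check_priors(model_priors)
  M <- length(model_priors)
  if (M < 2L) stop("need at least 2 models", call. = FALSE)
  H <- entropy_bits(model_priors)
  if (!is.finite(jsd) || jsd < -1e-9)
    stop("jsd must be a finite nonnegative scalar", call. = FALSE)
  if (jsd > H + 1e-9)
    stop(sprintf("jsd (%.6g bits) exceeds the prior entropy (%.6g bits)",
                 jsd, H), call. = FALSE)
  b <- max(H - jsd, 0)
  c(lower_bound = b^2 / (4 * (M - 1)), upper_bound = b / 2)
}

#' Selection risk report from Gaussian predictive densities
#'
#' Core computation behind [laplace_chernoff_risk()] and [family_risk()]:
#' given per-model Gaussian predictive moments, evaluates the Jensen-Shannon
#' divergence, the error-rate bounds, the Laplace-Chernoff risk `b_LC = H -
#' D_JS` (bits, reported unclipped: negative values indicate that the Laplace
#' approximation has pushed the divergence past the prior entropy, i.e. the
#' upper bound has broken down), and the matrix of pairwise
#' Kullback-Leibler divergences.
#'
#' @param predictives list of [gaussian_predictive()] objects.
#' @param model_priors prior model probabilities (default uniform).
#' @param method divergence method passed to [jensen_shannon()].
#' @param names optional model names for the KL matrix.
#' @param ... further arguments (e.g. `mc_samples`, `seed`) for
#'   [jensen_shannon()].
#' @return an object of class `risk_report` with fields `jsd`, `lower_bound`,
#'   `upper_bound`, `laplace_chernoff_risk`, `per_pair_kl`, `method`,
#'   `n_models` and `valid` (FALSE when the bound regime is broken; values
#'   are reported rather than clipped).
#' @export
risk_from_predictives <- function(predictives, model_priors = NULL,
                                  method = "laplace", names = NULL, ...) {
  d <- check_predictives(predictives)
  M <- length(predictives)
  if (is.null(model_priors)) model_priors <- rep(1 / M, M)
  model_priors <- check_priors(model_priors, M)
  H <- entropy_bits(model_priors)
  jsd <- jensen_shannon(predictives, model_priors, method = method, ...)
  se <- attr(jsd, "se")
  jsd <- as.numeric(jsd)
  b <- H - jsd
  valid <- b >= -1e-9
  if (!valid)
    warning(sprintf("Laplace-Chernoff bound regime broken (b_LC = %.4g bits < 0): high-discriminability regime",
                    b), call. = FALSE)
  bounds <- chernoff_bounds(min(jsd, H), model_priors)
  K <- matrix(0, M, M)
  for (i in seq_len(M)) for (j in seq_len(M)) if (i != j)
    K[i, j] <- kl_gaussian(predictives[[i]], predictives[[j]])
  if (!is.null(names)) dimnames(K) <- list(names, names)
  structure(list(jsd = jsd, jsd_se = se,
                 lower_bound = unname(bounds["lower_bound"]),
                 upper_bound = unname(bounds["upper_bound"]),
                 laplace_chernoff_risk = b,
                 prior_entropy = H, per_pair_kl = K,
                 method = method, n_models = M, dim = d, valid = valid),
            class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf("<risk_report: %d models, %d data dimension(s), method '%s'>\n",
              x$n_models, x$dim, x$method))
  cat(sprintf("  Jensen-Shannon divergence: %.4f bits (prior entropy %.4f)\n",
              x$jsd, x$prior_entropy))
  cat(sprintf("  Laplace-Chernoff risk:     %.4f bits%s\n",
              x$laplace_chernoff_risk,
              if (x$valid) "" else "  [bound regime broken]"))
  cat(sprintf("  error-rate bounds:         [%.4f, %.4f]\n",
              x$lower_bound, x$upper_bound))
  invisible(x)
}

#' Laplace-Chernoff risk of a design for a model comparison set
#'
#' Builds each model's Laplace-approximated prior predictive density under
#' the design and evaluates the Jensen-Shannon divergence, the error-rate
#' bounds and the Laplace-Chernoff risk `b_LC = H(m) - D_JS` (bits). Low risk
#' means the design separates the models' predictions well; `b_LC` tends to
#' its maximum `H(m)` (and the upper error bound to 0.5 for two equiprobable
#' models) as the predictive densities coincide. Deterministic given inputs.
#'
#' @param model_set a [model_set()].
#' @param design design passed to the models' observation mappings.
#' @param noise_mode see [laplace_predictive()].
#' @return a `risk_report` (see [risk_from_predictives()]) with the
#'   predictives attached as attribute `"predictives"`.
#' @export
laplace_chernoff_risk <- function(model_set, design = NULL,
                                  noise_mode = "expected-precision") {
  stopifnot(inherits(model_set, "model_set"))
  preds <- lapply(model_set$models, function(m) {
    tryCatch(laplace_predictive(m, design, noise_mode = noise_mode),
             error = function(e)
               stop(sprintf("predictive failure for model '%s': %s",
                            m$name, conditionMessage(e)), call. = FALSE))
  })
  rep_ <- risk_from_predictives(preds, model_set$model_priors,
                                method = "laplace", names = model_set$names)
  attr(rep_, "predictives") <- preds
  rep_
}

#' Exact selection error rate for two or more univariate predictives
#'
#' Evaluates the Bayes selection error rate `p(e|u) = 1 - integral of
#' max_m p(m) p(y|m,u) dy` by adaptive quadrature; this is the exact
#' quantity the Chernoff-type bounds sandwich, available in closed
#' integral form only for low-dimensional data.
#'
#' @param predictives list of 1-D [gaussian_predictive()] objects.
#' @param model_priors prior model probabilities (default uniform).
#' @return error probability; at most `1 - max(model_priors)` (0.5 for two
#'   equiprobable models).
#' @export
exact_error_rate_1d <- function(predictives, model_priors = NULL) {
  d <- check_predictives(predictives)
  if (d != 1L)
    stop("exact_error_rate_1d requires univariate densities", call. = FALSE)
  M <- length(predictives)
  if (is.null(model_priors)) model_priors <- rep(1 / M, M)
  model_priors <- check_priors(model_priors, M)
  mus <- vapply(predictives, function(p) p$mean, numeric(1))
  sds <- vapply(predictives, function(p) sqrt(p$cov[1, 1]), numeric(1))
  wdens <- function(y, m) model_priors[m] * dnorm(y, mus[m], sds[m])
  argmax_is <- function(y, m) {
    W <- vapply(seq_len(M), function(k) wdens(y, k), numeric(length(y)))
    W <- if (is.matrix(W)) W else matrix(W, nrow = 1L)
    ## ties broken by lowest index, matching the selection rule
    apply(W, 1L, which.max) == m
  }
  p_correct <- sum(vapply(seq_len(M), function(m) {
    ## integrate in the standardized variable of component m: numerically
    ## well conditioned even for widely separated means
    f <- function(z) {
      y <- mus[m] + sds[m] * z
      ifelse(argmax_is(y, m), model_priors[m] * dnorm(z), 0)
    }
    val <- try(integrate(f, -12, 12,
                         subdivisions = 2000L, rel.tol = 1e-10,
                         abs.tol = 1e-13, stop.on.error = FALSE)$value,
               silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val))
      stop("non-integrable predictive density", call. = FALSE)
    val
  }, numeric(1)))
  max(0, min(1, 1 - p_correct))
}

#' Posterior probability of a model selection error
#'
#' After selecting the maximum-a-posteriori model (ties broken by lowest
#' index), the probability that the selection is wrong is one minus the
#' largest posterior model probability.
#'
#' @param model_posteriors posterior probability vector over models.
#' @return error probability `1 - max(model_posteriors)`.
#' @export
posterior_error_probability <- function(model_posteriors) {
  model_posteriors <- check_priors(model_posteriors,
                                   what = "model_posteriors")
  1 - max(model_posteriors)
}

## family-level collapse of member predictives (moment-matched Gaussian)
collapse_families <- function(predictives, priors, labels) {
  fams <- unique(labels)
  fam_priors <- vapply(fams, function(f) sum(priors[labels == f]), numeric(1))
  fam_preds <- lapply(fams, function(f) {
    idx <- which(labels == f)
    w <- priors[idx] / sum(priors[idx])
    mm <- mix_moments(predictives[idx], w)
    gaussian_predictive(mm$mean, repair_pd(mm$cov))
  })
  list(families = fams, priors = fam_priors, predictives = fam_preds)
}

#' Laplace-Chernoff risk for comparing families of models
#'
#' Each family's predictive density is the within-family prior-weighted
#' mixture of its members' Laplace predictives (marginalizing over members);
#' by default the mixture is collapsed to its moment-matched Gaussian before
#' the Laplace-Chernoff formula is applied, with family priors equal to the
#' summed member priors.
#'
#' @param model_set a [model_set()].
#' @param partition family labels, one per model; defaults to the set's
#'   `family_labels`.
#' @param design design passed to the observation mappings.
#' @param noise_mode see [laplace_predictive()].
#' @return a `risk_report` over families (`method` records the mixture
#'   collapse), with family names attached.
#' @export
family_risk <- function(model_set, partition = NULL, design = NULL,
                        noise_mode = "expected-precision") {
  stopifnot(inherits(model_set, "model_set"))
  if (is.null(partition)) partition <- model_set$family_labels
  if (is.null(partition))
    stop("no family partition given and the model set has no family_labels",
         call. = FALSE)
  if (length(partition) != length(model_set$models))
    stop("partition must assign one family per model", call. = FALSE)
  if (length(unique(partition)) < 2L)
    stop("partition defines a single family: nothing to compare",
         call. = FALSE)
  preds <- lapply(model_set$models, laplace_predictive, design = design,
                  noise_mode = noise_mode)
  fam <- collapse_families(preds, model_set$model_priors, partition)
  rep_ <- risk_from_predictives(fam$predictives, fam$priors,
                                method = "laplace",
                                names = as.character(fam$families))
  rep_$method <- "laplace (moment-matched family collapse)"
  rep_$families <- fam$families
  attr(rep_, "predictives") <- fam$predictives
  rep_
}

## Monte-Carlo JSD between family-level mixtures (no Gaussian collapse);
## cross-check for the moment-matched family path
family_jsd_mc <- function(predictives, priors, labels, mc_samples = 2e4,
                          seed = 1) {
  fams <- unique(labels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fam_priors <- vapply(fams, function(f) sum(priors[labels == f]), numeric(1))
  fam_logdens <- function(Y, f) {
    idx <- which(labels == f)
    mixture_logdens(Y, predictives[idx], priors[idx] / sum(priors[idx]))
  }
  est <- 0
  for (fi in seq_along(fams)) {
    idx <- which(labels == fams[fi])
    w <- priors[idx] / sum(priors[idx])
    nf <- max(2L, round(mc_samples * fam_priors[fi]))
    comp <- sample(idx, nf, replace = TRUE, prob = w)
    tab <- tabulate(match(comp, idx), nbins = length(idx))
    Y <- do.call(rbind, lapply(seq_along(idx), function(k) {
      if (tab[k] == 0L) return(NULL)
      rmvn(tab[k], predictives[[idx[k]]]$mean, predictives[[idx[k]]]$cov)
    }))
    lf <- fam_logdens(Y, fams[fi])
    lmix_all <- vapply(seq_along(fams), function(fj)
      fam_logdens(Y, fams[fj]) + log(fam_priors[fj]), numeric(nrow(Y)))
    mx <- apply(lmix_all, 1L, max)
    lmix <- mx + log(rowSums(exp(lmix_all - mx)))
    est <- est + fam_priors[fi] * mean(lf - lmix)
  }
  est / LOG2
}
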