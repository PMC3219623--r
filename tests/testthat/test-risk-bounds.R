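test_that("Gaussian KL divergence matches a quadrature oracle", {
  expect_equal(kl_gaussian(g1d(0.3, 2), g1d(0.3, 2)), 0)
  p <- g1d(0); q <- g1d(1)
  f <- function(y) dnorm(y) * (dnorm(y, log = TRUE) -
                                 dnorm(y, 1, log = TRUE)) / log(2)
  oracle <- integrate(f, -12, 12, rel.tol = 1e-12)$value
  expect_equal(kl_gaussian(p, q), oracle, tolerance = 1e-6)
  expect_error(kl_gaussian(p, gaussian_predictive(c(0, 0), diag(2))),
               "dimension mismatch")
  expect_error(kl_gaussian(p, gaussian_predictive(0, matrix(0))),
               "singular")
})

test_that("Jensen-Shannon divergence has the right anchors and agreement", {
  ## identical densities
  expect_equal(jensen_shannon(list(g1d(2), g1d(2))), 0)
  ## fully separated equiprobable mixture: 1 bit
  sep <- list(g1d(-5e5), g1d(5e5))
  expect_equal(jensen_shannon(sep, method = "quadrature"), 1,
               tolerance = 1e-6)
  ## laplace, quadrature and stratified monte-carlo agree for a weakly
  ## separated pair (means 0/1, unit variance)
  pair <- list(g1d(0), g1d(1))
  jq <- jensen_shannon(pair, method = "quadrature")
  jl <- jensen_shannon(pair, method = "laplace")
  jm <- jensen_shannon(pair, method = "monte-carlo", mc_samples = 1e6,
                       seed = 7)
  se <- attr(jm, "se")
  expect_lt(abs(as.numeric(jm) - jq), 3 * se)
  expect_lt(abs(jl - as.numeric(jm)), 3 * se + 5e-4)
  ## units flag
  expect_equal(jensen_shannon(pair, units = "nats"), jl * log(2))
  ## quadrature is 1-D only; monte-carlo needs a seed
  two_d <- list(gaussian_predictive(c(0, 0), diag(2)),
                gaussian_predictive(c(1, 1), diag(2)))
  expect_error(jensen_shannon(two_d, method = "quadrature"), "univariate")
  expect_error(jensen_shannon(pair, method = "monte-carlo"), "seed")
})

test_that("JSD stays below the prior entropy across random cases", {
  set.seed(11)
  for (rep in 1:20) {
    M <- sample(2:4, 1)
    preds <- lapply(seq_len(M), function(i) g1d(rnorm(1, 0, 2),
                                                exp(rnorm(1))))
    w <- rexp(M); w <- w / sum(w)
    js <- jensen_shannon(preds, w, method = "quadrature")
    H <- -sum(w * log2(w))
    expect_lte(js, H + 1e-6)
    expect_gte(js, -1e-12)
  }
})

test_that("Chernoff-type bounds behave at their analytic anchors", {
  ## two equiprobable models: jsd 0 gives upper bound 0.5; jsd 1 bit
  ## collapses both bounds to 0
  b0 <- chernoff_bounds(0, c(0.5, 0.5))
  expect_equal(unname(b0["upper_bound"]), 0.5)
  b1 <- chernoff_bounds(1, c(0.5, 0.5))
  expect_equal(unname(b1), c(0, 0))
  ## monotonically decreasing in jsd
  js_grid <- seq(0, 1, by = 0.1)
  ub <- vapply(js_grid, function(j)
    chernoff_bounds(j, c(0.5, 0.5))["upper_bound"], numeric(1))
  lb <- vapply(js_grid, function(j)
    chernoff_bounds(j, c(0.5, 0.5))["lower_bound"], numeric(1))
  expect_true(all(diff(ub) < 0) && all(diff(lb) < 0))
  expect_true(all(lb <= ub))
  ## jsd above the prior entropy is a domain error
  expect_error(chernoff_bounds(1.2, c(0.5, 0.5)), "exceeds")
})

test_that("exact 1-D error rate matches closed forms", {
  expect_equal(exact_error_rate_1d(list(g1d(0), g1d(0))), 0.5)
  expect_lt(exact_error_rate_1d(list(g1d(0), g1d(1e6))), 1e-12)
  ## equal-variance Gaussians, means 0/1: Bayes error Phi(-1/2)
  expect_equal(exact_error_rate_1d(list(g1d(0), g1d(1))), pnorm(-0.5),
               tolerance = 1e-9)
  ## asymmetric priors shift the error below 1 - max prior
  e <- exact_error_rate_1d(list(g1d(0), g1d(1)), c(0.8, 0.2))
  expect_lt(e, 0.2)
})

test_that("posterior error probability is one minus the top posterior", {
  expect_equal(posterior_error_probability(c(1, 0)), 0)
  expect_equal(posterior_error_probability(c(0.5, 0.5)), 0.5)
  expect_equal(posterior_error_probability(c(0.9, 0.1)), 0.1)
})

test_that("bound sandwich holds for weak discriminability and breakdown is flagged", {
  ## weakly discriminable pairs: lower <= exact <= upper
  for (dm in c(0.2, 0.5, 1, 1.5)) {
    pair <- list(g1d(0), g1d(dm))
    r <- risk_from_predictives(pair)
    e <- exact_error_rate_1d(pair)
    expect_true(r$valid)
    expect_lte(r$lower_bound, e + 1e-9)
    expect_gte(r$upper_bound, e - 1e-9)
  }
  ## high discriminability: the report flags the broken regime instead of
  ## clipping the risk
  far <- list(g1d(0), g1d(8))
  r <- suppressWarnings(risk_from_predictives(far))
  expect_false(r$valid)
  expect_lt(r$laplace_chernoff_risk, 0)
  expect_warning(risk_from_predictives(far), "broken")
})

test_that("risk report carries a zero-diagonal nonnegative KL matrix", {
  preds <- list(g1d(0, 1), g1d(1, 2), g1d(-1, 0.5))
  r <- risk_from_predictives(preds)
  expect_equal(diag(r$per_pair_kl), rep(0, 3))
  expect_true(all(r$per_pair_kl >= 0))
  expect_equal(r$n_models, 3L)
})

test_that("two identical models put the risk at its maximum", {
  pair <- list(g1d(0.7, 1.3), g1d(0.7, 1.3))
  r <- risk_from_predictives(pair)
  expect_equal(r$laplace_chernoff_risk, 1)   # = prior entropy for 2 models
  expect_equal(r$upper_bound, 0.5)
})

test_that("equal-covariance two-model risk reduces to the contrast-resolution form", {
  ## b_LC = 1 - (1/2) log2(1 + dg^2 / (4 Q)) for equal variances Q
  for (dg in c(0.3, 1, 2.5)) for (Q in c(0.5, 1, 4)) {
    r <- suppressWarnings(risk_from_predictives(list(g1d(0, Q), g1d(dg, Q))))
    expect_equal(r$laplace_chernoff_risk, 1 - 0.5 * log2(1 + dg^2 / (4 * Q)),
                 tolerance = 1e-12)
  }
})

test_that("error rate grows with the number of equally spaced models", {
  errs <- vapply(2:6, function(M)
    exact_error_rate_1d(lapply(seq_len(M), function(k) g1d(k - 1))),
    numeric(1))
  expect_nondecreasing(errs)
  ## and the Laplace-Chernoff risk follows
  risks <- vapply(2:6, function(M) suppressWarnings(
    risk_from_predictives(lapply(seq_len(M), function(k) g1d(k - 1)))
  )$laplace_chernoff_risk, numeric(1))
  expect_nondecreasing(risks)
})

test_that("error bounds shrink as the data dimension grows at fixed contrast", {
  ub <- vapply(c(1, 2, 4, 8), function(nn) suppressWarnings(
    risk_from_predictives(list(gaussian_predictive(rep(0, nn), diag(nn)),
                               gaussian_predictive(rep(1, nn), diag(nn))))
  )$upper_bound, numeric(1))
  expect_nondecreasing(rev(ub))
})

test_that("family risk collapses correctly and validates its partition", {
  preds <- list(g1d(0), g1d(0.2), g1d(3), g1d(3.3))
  ## singleton families reproduce the model-level report
  rs <- suppressWarnings(risk_from_predictives(preds))
  ms <- model_set(lapply(1:4, function(i)
    ng_model(paste0("m", i), local({mu <- preds[[i]]$mean
      function(th, u) mu + 0 * th}), 0, 0, noise_cov = 1)))
  r_model <- suppressWarnings(laplace_chernoff_risk(ms, NULL,
                                                    noise_mode = "fixed"))
  r_singleton <- suppressWarnings(family_risk(ms, letters[1:4], NULL,
                                              noise_mode = "fixed"))
  expect_equal(r_singleton$laplace_chernoff_risk,
               r_model$laplace_chernoff_risk, tolerance = 1e-10)
  ## a proper 2-family partition differs from the model-level risk and has
  ## family priors summing the members
  r_fam <- suppressWarnings(family_risk(ms, c("f1", "f1", "f2", "f2"), NULL,
                                        noise_mode = "fixed"))
  expect_equal(r_fam$n_models, 2L)
  expect_false(isTRUE(all.equal(r_fam$laplace_chernoff_risk,
                                r_model$laplace_chernoff_risk)))
  expect_error(family_risk(ms, rep("f", 4), NULL), "single family")
})

test_that("moment-matched family risk ranks designs like the Monte-Carlo mixture JSD", {
  set.seed(3)
  labels <- c("f1", "f1", "f2", "f2")
  mm <- mc <- numeric(5)
  for (k in 1:5) {
    centers <- rnorm(4, 0, 2)
    preds <- lapply(centers, function(m) g1d(m, exp(rnorm(1, 0, 0.3))))
    fam <- bmsdesign:::collapse_families(preds, rep(0.25, 4), labels)
    mm[k] <- suppressWarnings(
      risk_from_predictives(fam$predictives, fam$priors))$jsd
    mc[k] <- bmsdesign:::family_jsd_mc(preds, rep(0.25, 4), labels,
                                       mc_samples = 2e4, seed = k)
  }
  expect_equal(cor(rank(mm), rank(mc), method = "spearman"), 1)
})
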