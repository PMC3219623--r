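## closed-form log marginal likelihood of a linear-Gaussian model with
## known residual precision: the conjugate-algebra oracle
linear_log_evidence <- function(X, y, eta, Sth, lambda) {
  Q <- X %*% Sth %*% t(X) + diag(1 / lambda, nrow(X))
  r <- y - drop(X %*% eta)
  -0.5 * (nrow(X) * log(2 * pi) +
            as.numeric(determinant(Q)$modulus) +
            drop(crossprod(r, solve(Q, r))))
}

test_that("free energy equals the exact log evidence for linear-Gaussian models", {
  set.seed(7)
  X <- matrix(rnorm(40), 20, 2)
  lam <- 4
  Sth <- diag(c(1, 2))
  eta <- c(0.5, -0.2)
  m <- ng_model("lin", function(th, u) drop(X %*% th), eta, Sth,
                noise_cov = 1 / lam)
  y <- drop(X %*% c(1, 0.3)) + rnorm(20, 0, 1 / sqrt(lam))
  fit <- invert_vl(m, y, config = list(fix_precision = lam, tol = 1e-8))
  expect_lt(abs(fit$free_energy - linear_log_evidence(X, y, eta, Sth, lam)),
            1e-3)
  ## and the posterior matches the conjugate Gaussian posterior
  P <- lam * crossprod(X) + solve(Sth)
  mu <- solve(P, lam * crossprod(X, y) + solve(Sth) %*% eta)
  expect_equal(fit$posterior_mean, drop(mu), tolerance = 1e-6)
  expect_equal(fit$posterior_cov, solve(P), tolerance = 1e-6)
})

test_that("accepted-step free-energy traces never decrease", {
  set.seed(8)
  X <- matrix(rnorm(60), 30, 2)
  m <- ng_model("lin", function(th, u) drop(X %*% th), c(0, 0), diag(2),
                noise_precision_prior = c(shape = 1, scale = 2))
  y <- drop(X %*% c(0.7, -1.2)) + rnorm(30, 0, 0.5)
  fit <- invert_vl(m, y, config = list(tol = 1e-6))
  expect_nondecreasing(fit$free_energy_trace, tol = 1e-10)
  ## a mildly nonlinear model
  mn <- ng_model("nl", function(th, u) sin(X %*% th)[, 1], c(0.2, 0.2),
                 diag(2), noise_precision_prior = c(shape = 1, scale = 2))
  yn <- sin(X %*% c(0.5, -0.3))[, 1] + rnorm(30, 0, 0.3)
  fitn <- invert_vl(mn, yn, config = list(tol = 1e-6))
  expect_nondecreasing(fitn$free_energy_trace, tol = 1e-10)
  expect_true(fitn$converged)
})

test_that("zero free parameters leave only the expected log likelihood", {
  set.seed(9)
  y <- rnorm(12)
  lam <- 2.5
  m0 <- ng_model("null", function(th, u) rep(0, 12), numeric(0),
                 matrix(0, 0, 0), noise_cov = 1 / lam)
  fit <- invert_vl(m0, y, config = list(fix_precision = lam))
  expect_equal(fit$free_energy, sum(dnorm(y, 0, 1 / sqrt(lam), log = TRUE)),
               tolerance = 1e-10)
})

test_that("model posteriors follow softmax arithmetic with stable ties", {
  mp <- model_posterior(c(-10, -10))
  expect_equal(mp$posterior, c(0.5, 0.5))
  expect_equal(mp$selected, 1L)     # lowest index on ties
  mp2 <- model_posterior(c(log(9), 0))
  expect_equal(mp2$posterior, c(0.9, 0.1), tolerance = 1e-12)
  expect_equal(posterior_error_probability(mp2$posterior),
               1 - max(mp2$posterior))
  ## huge free energies do not overflow
  mp3 <- model_posterior(c(5000, 4990))
  expect_equal(mp3$posterior[1], 1 / (1 + exp(-10)), tolerance = 1e-12)
  expect_error(model_posterior(c(1, NaN)), "finite")
})

test_that("nested linear models rank by free energy like exact Bayes factors", {
  set.seed(10)
  X <- matrix(rnorm(75), 25, 3)
  lam <- 2
  y <- drop(X %*% c(1, 0.5, 0)) + rnorm(25, 0, 1 / sqrt(lam))
  Fs <- lml <- numeric(3)
  for (p in 1:3) {
    Xp <- X[, 1:p, drop = FALSE]
    m <- ng_model(paste0("m", p), local({Xp <- Xp
      function(th, u) drop(Xp %*% th)}), rep(0, p), diag(p),
      noise_cov = 1 / lam)
    Fs[p] <- invert_vl(m, y, config = list(fix_precision = lam,
                                           tol = 1e-8))$free_energy
    lml[p] <- linear_log_evidence(Xp, y, rep(0, p), diag(p), lam)
  }
  expect_equal(order(Fs), order(lml))
  expect_equal(Fs, lml, tolerance = 1e-3)
})

test_that("linear posteriors never exceed the prior in Loewner order", {
  set.seed(12)
  X <- matrix(rnorm(40), 20, 2)
  Sth <- crossprod(matrix(rnorm(4), 2)) + diag(2)
  m <- ng_model("lin", function(th, u) drop(X %*% th), c(0, 0), Sth,
                noise_cov = 0.5)
  y <- rnorm(20)
  fit <- invert_vl(m, y, config = list(fix_precision = 2))
  ev <- eigen(Sth - fit$posterior_cov, symmetric = TRUE,
              only.values = TRUE)$values
  expect_true(all(ev >= -1e-10))
})

test_that("data length mismatches are caught before inversion", {
  m <- linear_model(diag(3))
  expect_error(invert_vl(m, rnorm(5)), "does not match")
})
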