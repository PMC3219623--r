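two_region_chain <- function(a21 = 0.6, a12 = 0) {
  dcm_spec(matrix(c(-1, a21, a12, -1), 2), C = matrix(c(1, 0), 2))
}

test_that("neural flow obeys its algebraic structure", {
  spec <- dcm_spec(matrix(c(-1, 0.4, 0.2, -1), 2),
                   B = list(matrix(c(0, 0.5, 0, 0), 2)),
                   C = matrix(c(1, 0), 2))
  expect_equal(neural_flow(c(0, 0), 0, spec), c(0, 0))
  ## input to region 1 only: instantaneous flow only in region 1
  expect_equal(neural_flow(c(0, 0), 1, spec), c(1, 0))
  ## bilinear term: flow(x, u=1) - flow(x, u=0) = B1 x + C
  x <- c(0.3, -0.2)
  expect_equal(neural_flow(x, 1, spec) - neural_flow(x, 0, spec),
               drop(spec$B[[1]] %*% x + spec$C))
  expect_error(neural_flow(c(0, 0, 0), 1, spec), "dimension mismatch")
})

test_that("gating matrices enter the flow when present", {
  D <- list(matrix(0, 2, 2), matrix(c(0.3, 0, 0, 0), 2))
  spec <- dcm_spec(matrix(c(-1, 0, 0, -1), 2), C = matrix(c(1, 0), 2),
                   D = D)
  x <- c(0.5, 2)
  expect_equal(neural_flow(x, 0, spec),
               drop((spec$A + x[2] * D[[2]]) %*% x))
})

test_that("balloon flow has the resting fixed point and the right signs", {
  pars <- list(kappa = 0.64, gamma = 0.32, tau = 2, alpha = 0.32, E0 = 0.32)
  rest <- c(0, 1, 1, 1)
  expect_equal(hemodynamic_flow(rest, 0, pars), rest * 0,
               tolerance = 1e-12, ignore_attr = TRUE)
  ## sustained neural input: the vasodilatory signal, then inflow, rise
  d1 <- hemodynamic_flow(rest, 1, pars)
  expect_gt(d1[1], 0)
  d2 <- hemodynamic_flow(c(0.5, 1, 1, 1), 1, pars)
  expect_gt(d2[2], 0)
  expect_error(hemodynamic_flow(c(0, 1, -1, 1), 0, pars), "positive")
})

test_that("BOLD observation is zero at rest and rises when dHb falls", {
  obs <- list(E0 = 0.32, V0 = 0.04)
  expect_equal(bold_observation(c(0, 1, 1, 1), obs), 0)
  expect_gt(bold_observation(c(0, 1, 1, 0.9), obs), 0)
})

test_that("a DCM has five states per region and holds rest under zero input", {
  spec <- two_region_chain()
  expect_equal(spec$n_states, 10L)
  d0 <- design_spec(matrix(0, 1, 400), 0.1, 1.3)
  path <- integrate_dcm(spec, d0)
  expect_equal(nrow(path$states), 10L)
  expect_equal(max(abs(path$bold)), 0)
  expect_equal(path$states[, 400], path$states[, 1])
})

test_that("the BOLD response is delayed and regions respond in causal order", {
  spec <- two_region_chain(a21 = 0.8)
  u <- numeric(800); u[1:160] <- 1          # 16 s box input
  d <- design_spec(matrix(u, 1), 0.1, 1.3)
  path <- integrate_dcm(spec, d)
  b1 <- path$bold_micro[1, ]; b2 <- path$bold_micro[2, ]
  ## peak lags the onset by several seconds (hemodynamic delay)
  expect_gt(which.max(b1) * 0.1, 3)
  ## downstream region peaks after the driven one
  expect_gt(which.max(b2), which.max(b1))
  ## post-stimulus return to rest: all states near rest 60 s after offset
  rest <- path$states[, 1]
  late <- path$states[, 770]                # 16 s + 61 s
  expect_lt(max(abs(late - rest)), 0.01)
})

test_that("halving the integration step leaves the BOLD output unchanged", {
  fx <- feedback_fixture(seed = 2)
  spec <- fx$set$models[[1]]$dcm_spec
  dA <- fx$design
  u2 <- dA$inputs[, rep(seq_len(ncol(dA$inputs)), each = 2), drop = FALSE]
  dB <- design_spec(u2, dt = 0.05, TR = 1.3)
  yA <- integrate_dcm(spec, dA)$bold
  yB <- integrate_dcm(spec, dB)$bold
  expect_equal(dim(yA), dim(yB))
  expect_lt(sqrt(mean((yA - yB)^2)) / sqrt(mean(yB^2)), 1e-3)
})

test_that("weak-input responses are first-order in the driving gain", {
  spec1 <- two_region_chain()
  u <- numeric(600); u[1:20] <- 1
  d <- design_spec(matrix(u, 1), 0.1, 1.3)
  spec_small <- spec1; spec_small$C[1, 1] <- 0.05
  spec_double <- spec1; spec_double$C[1, 1] <- 0.1
  p1 <- max(integrate_dcm(spec_small, d)$states[1, ])
  p2 <- max(integrate_dcm(spec_double, d)$states[1, ])
  expect_equal(p2 / p1, 2, tolerance = 0.05)
})

test_that("hemodynamic refractoriness damps a closely following pulse", {
  spec <- two_region_chain()
  u_pair <- numeric(600); u_pair[1:10] <- 1; u_pair[31:40] <- 1
  u_one <- numeric(600); u_one[1:10] <- 1
  d2 <- design_spec(matrix(u_pair, 1), 0.1, 1.3)
  d1 <- design_spec(matrix(u_one, 1), 0.1, 1.3)
  b_pair <- integrate_dcm(spec, d2)$bold_micro[1, ]
  b_one <- integrate_dcm(spec, d1)$bold_micro[1, ]
  second <- b_pair - b_one   # response attributable to the second pulse
  expect_lt(max(second), max(b_one))
})

test_that("unstable parameterizations raise an instability error", {
  fm <- bmsdesign:::free_mask_empty(2L, 1L)
  fm$A[1, 2] <- fm$A[2, 1] <- TRUE
  expect_warning(
    spec <- dcm_spec(matrix(c(-1, 3, 3, -1), 2), C = matrix(c(1, 0), 2),
                     free = fm),
    "not stable")
  u <- numeric(1500); u[1:160] <- 1
  d <- design_spec(matrix(u, 1), 0.1, 1.3)
  expect_error(integrate_dcm(spec, d), "diverged")
})

test_that("the compiled nonlinear Gaussian model reproduces the forward model", {
  fx <- feedback_fixture(seed = 4)
  m <- fx$set$models[[1]]
  eta <- dcm_prior_mean(m$dcm_spec)
  y <- m$observation_mapping(eta, fx$design)
  path <- integrate_dcm(m$dcm_spec, fx$design)
  expect_equal(y, as.numeric(t(path$bold)))
  ## binding a design at compilation fixes and validates the data dimension
  m2 <- dcm_as_ng_model(m$dcm_spec, design = fx$design)
  expect_equal(m2$n_y, 2L * fx$design$n_scans)
  expect_null(m$n_y)   # design-dependent until a design is bound
})

test_that("datasets are reproducible, tend to noiseless data, and have the right noise", {
  spec <- two_region_chain()
  d <- make_blocked_design(16, session_length = 100, seed = 3)
  a <- simulate_dataset(spec, d, noise_precision = 1, seed = 9)
  b <- simulate_dataset(spec, d, noise_precision = 1, seed = 9)
  expect_identical(a$y, b$y)
  clean <- simulate_dataset(spec, d, noise_precision = 1e12, seed = 9)
  path <- integrate_dcm(spec, d)
  expect_equal(clean$y, path$bold, tolerance = 1e-4)
  ## empirical residual variance across ~1e4 values within 5 percent
  dl <- design_spec(matrix(0, 1, 65100), 0.1, 1.3)
  ds <- simulate_dataset(spec, dl, noise_precision = 4, seed = 10)
  expect_equal(length(ds$y) >= 1e4, TRUE)
  expect_equal(var(as.numeric(ds$y)), 0.25, tolerance = 0.05)
})

test_that("free-parameter bookkeeping applies theta consistently", {
  fx <- feedback_fixture()
  spec <- fx$set$models[[1]]$dcm_spec
  eta <- dcm_prior_mean(spec)
  expect_named(eta)
  th <- eta + 0.1
  spec2 <- bmsdesign:::dcm_apply_theta(spec, th)
  expect_equal(spec2$A[2, 1], spec$A[2, 1] + 0.1)
  expect_equal(spec2$hemo$kappa, spec$hemo$kappa * exp(0.1))
  expect_error(bmsdesign:::dcm_apply_theta(spec, th[-1]), "length")
})
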