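## Deterministic bilinear DCM forward model for small networks: neural
## evolution, balloon hemodynamics, BOLD observation, RK4 integration and
## dataset simulation.

#' Default balloon-model hemodynamic parameters
#'
#' Standard published DCM conventions: vasodilatory signal decay 0.64 1/s,
#' autoregulatory feedback 0.32 1/s, mean transit time 2 s, vessel stiffness
#' exponent 0.32, resting oxygen extraction fraction 0.32, resting venous
#' volume fraction 0.04. All per-region and overridable.
#'
#' @param n_regions number of regions.
#' @return list of per-region parameter vectors `kappa`, `gamma`, `tau`,
#'   `alpha`, `E0`, `V0`.
#' @export
hemo_defaults <- function(n_regions) {
  list(kappa = rep(0.64, n_regions), gamma = rep(0.32, n_regions),
       tau = rep(2, n_regions), alpha = rep(0.32, n_regions),
       E0 = rep(0.32, n_regions), V0 = rep(0.04, n_regions))
}

## empty free-parameter mask
free_mask_empty <- function(n, n_inputs, has_d = FALSE) {
  list(A = matrix(FALSE, n, n),
       B = replicate(n_inputs, matrix(FALSE, n, n), simplify = FALSE),
       C = matrix(FALSE, n, n_inputs),
       D = if (has_d) replicate(n, matrix(FALSE, n, n), simplify = FALSE),
       hemo_decay = rep(FALSE, n), hemo_transit = rep(FALSE, n),
       obs_gain = rep(FALSE, n))
}

#' Bilinear DCM specification
#'
#' Coupling structure of a small network model: between-region coupling `A`
#' (Hz), one input-dependent modulation matrix `B[[j]]` per input (Hz), input
#' driving gains `C` (n-by-n_inputs, Hz), optional per-region gating matrices
#' `D[[k]]` (Hz), balloon hemodynamic parameters and BOLD observation
#' parameters. `free` marks which entries are estimated (their current values
#' serve as prior means); hemodynamic decay/transit and per-region BOLD gain
#' are estimated as log-scale multipliers with prior mean 0.
#'
#' @param A n-by-n coupling matrix; diagonal entries must be <= 0
#'   (self-inhibition). Stability of the linearized system at rest is checked
#'   and a warning issued otherwise.
#' @param B list of n-by-n modulation matrices, one per input.
#' @param C n-by-n_inputs driving-gain matrix.
#' @param D optional list of n gating matrices (off by default).
#' @param hemo hemodynamic parameters, see [hemo_defaults()].
#' @param obs_gain fixed per-region multiplicative BOLD gain (default 1).
#' @param free free-parameter mask; see Details. By default nothing is free.
#' @return an object of class `dcm_spec`.
#' @export
dcm_spec <- function(A, B = NULL, C, D = NULL, hemo = NULL, obs_gain = NULL,
                     free = NULL) {
  A <- as.matrix(A)
  n <- nrow(A)
  stopifnot(ncol(A) == n)
  C <- as.matrix(C)
  if (nrow(C) != n) stop("C must have n_regions rows", call. = FALSE)
  n_inputs <- ncol(C)
  if (is.null(B)) B <- replicate(n_inputs, matrix(0, n, n), simplify = FALSE)
  if (length(B) != n_inputs)
    stop(sprintf("need one B matrix per input (|B| = %d, n_inputs = %d)",
                 length(B), n_inputs), call. = FALSE)
  B <- lapply(B, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == n)) stop("each B must be n x n", call. = FALSE)
    m
  })
  if (!is.null(D)) {
    if (length(D) != n)
      stop("D must contain one gating matrix per region", call. = FALSE)
    D <- lapply(D, function(m) {
      m <- as.matrix(m)
      if (!all(dim(m) == n)) stop("each D must be n x n", call. = FALSE)
      m
    })
  }
  if (any(diag(A) > 0))
    stop("A diagonal entries must be <= 0 (self-inhibition)", call. = FALSE)
  ev <- eigen(A, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    warning("linearized system at rest is not stable for the prior mean (some Re(eig(A)) >= 0)",
            call. = FALSE)
  if (is.null(hemo)) hemo <- hemo_defaults(n)
  stopifnot(all(lengths(hemo) == n))
  if (is.null(obs_gain)) obs_gain <- rep(1, n)
  if (is.null(free)) free <- free_mask_empty(n, n_inputs, !is.null(D))
  structure(list(n_regions = n, n_inputs = n_inputs, A = A, B = B, C = C,
                 D = D, hemo = hemo, obs_gain = obs_gain, free = free,
                 n_states = 5L * n),
            class = "dcm_spec")
}

#' @export
print.dcm_spec <- function(x, ...) {
  cat(sprintf("<dcm_spec: %d regions (%d states), %d inputs, %d free parameter(s)>\n",
              x$n_regions, x$n_states, x$n_inputs, length(dcm_prior_mean(x))))
  invisible(x)
}

#' Experimental design: input time courses on a microtime grid
#'
#' @param inputs n_inputs-by-T matrix of input values `u(t)` sampled every
#'   `dt` seconds (a vector is taken as a single input).
#' @param dt microtime step in seconds (> 0).
#' @param TR observation (scan) interval in seconds; must be an integer
#'   multiple of `dt`.
#' @param sample_idx microtime indices at which scans are acquired; defaults
#'   to every `TR/dt`-th grid point.
#' @param annotations free-form list (epoch duration, jitter seed, condition
#'   labels, ...).
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(inputs, dt, TR, sample_idx = NULL,
                        annotations = list()) {
  if (!is.matrix(inputs)) inputs <- matrix(inputs, nrow = 1L)
  if (any(!is.finite(inputs))) stop("inputs must be finite", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  step <- TR / dt
  if (abs(step - round(step)) > 1e-8)
    stop("TR must be an integer multiple of dt", call. = FALSE)
  step <- as.integer(round(step))
  T_ <- ncol(inputs)
  ## grid column t holds the state at time (t - 1) * dt, so the scan at
  ## time TR * k sits at column TR * k / dt + 1
  if (is.null(sample_idx)) sample_idx <- seq(step + 1L, T_, by = step)
  if (any(sample_idx < 1L | sample_idx > T_))
    stop("sample_idx out of the time grid", call. = FALSE)
  structure(list(inputs = inputs, dt = dt, TR = TR,
                 n_inputs = nrow(inputs), n_time = T_,
                 sample_idx = as.integer(sample_idx),
                 n_scans = length(sample_idx),
                 times = (seq_len(T_) - 1L) * dt,
                 annotations = annotations),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design_spec: %d input(s), %.1f s at dt = %g s, TR = %g s (%d scans)>\n",
              x$n_inputs, x$n_time * x$dt, x$dt, x$TR, x$n_scans))
  invisible(x)
}

#' Neural evolution function of the bilinear DCM
#'
#' `dx/dt = (A + sum_j u_j B_j + sum_k x_k D_k) x + C u` (Hz); the gating
#' term is omitted when the specification carries no D matrices.
#'
#' @param x_neural neural state vector (one entry per region).
#' @param u input vector (one entry per input).
#' @param spec a [dcm_spec()].
#' @return derivative vector in Hz.
#' @export
neural_flow <- function(x_neural, u, spec) {
  stopifnot(inherits(spec, "dcm_spec"))
  if (length(x_neural) != spec$n_regions || length(u) != spec$n_inputs)
    stop("dimension mismatch between states/inputs and the DCM specification",
         call. = FALSE)
  J <- spec$A
  for (j in seq_len(spec$n_inputs))
    if (u[j] != 0) J <- J + u[j] * spec$B[[j]]
  if (!is.null(spec$D))
    for (k in seq_len(spec$n_regions))
      if (x_neural[k] != 0) J <- J + x_neural[k] * spec$D[[k]]
  drop(J %*% x_neural + spec$C %*% u)
}

#' Balloon-model hemodynamic flow for one region
#'
#' Standard vasodilatory-signal / inflow / venous-volume / deoxyhemoglobin
#' cascade driven by neural activity; at rest (`s = 0, f = v = q = 1`) with
#' zero neural input the flow is identically zero.
#'
#' @param hemo_states vector `c(s, f, v, q)`; `v` and `q` must be positive.
#' @param x_neural_region scalar neural activity of the region.
#' @param hemo_params list with scalars `kappa`, `gamma`, `tau`, `alpha`,
#'   `E0`.
#' @return derivative 4-vector.
#' @export
hemodynamic_flow <- function(hemo_states, x_neural_region, hemo_params) {
  s <- hemo_states[1]; f <- hemo_states[2]
  v <- hemo_states[3]; q <- hemo_states[4]
  if (v <= 0 || q <= 0)
    stop("volume and deoxyhemoglobin states must be positive", call. = FALSE)
  k <- hemo_params
  E <- 1 - (1 - k$E0)^(1 / max(f, 1e-6))
  c(s = x_neural_region - k$kappa * s - k$gamma * (f - 1),
    f = s,
    v = (f - v^(1 / k$alpha)) / k$tau,
    q = (max(f, 1e-6) * E / k$E0 - v^(1 / k$alpha) * q / v) / k$tau)
}

#' Static BOLD observation equation
#'
#' Percent signal change from venous volume and deoxyhemoglobin:
#' `y = 100 gain V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))` with
#' `k1 = 7 E0`, `k2 = 2`, `k3 = 2 E0 - 0.2`. Zero at resting states; a
#' decrease in deoxyhemoglobin at constant volume raises the signal.
#'
#' @param hemo_states vector `c(s, f, v, q)` or a 4-row matrix of states.
#' @param obs_params list with `E0`, `V0` and optional `gain` (default 1).
#' @return BOLD value(s) in percent signal change.
#' @export
bold_observation <- function(hemo_states, obs_params) {
  E0 <- obs_params$E0; V0 <- obs_params$V0
  gain <- if (is.null(obs_params$gain)) 1 else obs_params$gain
  st <- if (is.matrix(hemo_states)) hemo_states else matrix(hemo_states)
  v <- st[3, ]; q <- st[4, ]
  k1 <- 7 * E0; k2 <- 2; k3 <- 2 * E0 - 0.2
  100 * gain * V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
}

## ---- free-parameter machinery -------------------------------------------

dcm_param_names <- function(spec) {
  f <- spec$free
  nm <- c(
    sprintf("A[%d,%d]", row(f$A)[f$A], col(f$A)[f$A]),
    unlist(lapply(seq_along(f$B), function(j)
      sprintf("B%d[%d,%d]", j, row(f$B[[j]])[f$B[[j]]],
              col(f$B[[j]])[f$B[[j]]]))),
    sprintf("C[%d,%d]", row(f$C)[f$C], col(f$C)[f$C]),
    if (!is.null(f$D)) unlist(lapply(seq_along(f$D), function(k)
      sprintf("D%d[%d,%d]", k, row(f$D[[k]])[f$D[[k]]],
              col(f$D[[k]])[f$D[[k]]]))),
    sprintf("hemo_decay[%d]", which(f$hemo_decay)),
    sprintf("hemo_transit[%d]", which(f$hemo_transit)),
    sprintf("obs_gain[%d]", which(f$obs_gain)))
  nm
}

#' Prior mean of the free parameters of a DCM specification
#'
#' Free neural entries take their current values in the specification as
#' prior means; hemodynamic and observation log-multipliers have prior
#' mean 0.
#'
#' @param spec a [dcm_spec()].
#' @return named numeric vector.
#' @export
dcm_prior_mean <- function(spec) {
  f <- spec$free
  th <- c(spec$A[f$A],
          unlist(Map(function(b, m) b[m], spec$B, f$B)),
          spec$C[f$C],
          if (!is.null(f$D)) unlist(Map(function(d, m) d[m], spec$D, f$D)),
          rep(0, sum(f$hemo_decay)), rep(0, sum(f$hemo_transit)),
          rep(0, sum(f$obs_gain)))
  th <- as.numeric(th)
  names(th) <- dcm_param_names(spec)
  th
}

## instantiate the specification at a free-parameter vector
dcm_apply_theta <- function(spec, theta) {
  f <- spec$free
  k <- 0L
  take <- function(n) {
    if (n == 0L) return(numeric(0))
    out <- theta[(k + 1L):(k + n)]; k <<- k + n; out
  }
  spec$A[f$A] <- take(sum(f$A))
  for (j in seq_along(spec$B)) spec$B[[j]][f$B[[j]]] <- take(sum(f$B[[j]]))
  spec$C[f$C] <- take(sum(f$C))
  if (!is.null(f$D))
    for (d in seq_along(spec$D)) spec$D[[d]][f$D[[d]]] <- take(sum(f$D[[d]]))
  dec <- take(sum(f$hemo_decay))
  spec$hemo$kappa[f$hemo_decay] <- spec$hemo$kappa[f$hemo_decay] * exp(dec)
  tra <- take(sum(f$hemo_transit))
  spec$hemo$tau[f$hemo_transit] <- spec$hemo$tau[f$hemo_transit] * exp(tra)
  g <- take(sum(f$obs_gain))
  spec$obs_gain[f$obs_gain] <- spec$obs_gain[f$obs_gain] * exp(g)
  if (k != length(theta))
    stop(sprintf("theta has length %d, expected %d", length(theta), k),
         call. = FALSE)
  spec
}

## ---- integration ---------------------------------------------------------

#' Integrate a DCM from rest
#'
#' Fixed-step 4th-order Runge-Kutta integration of the coupled neural and
#' hemodynamic states on the design's microtime grid, starting from the
#' resting fixed point, with the BOLD observation evaluated along the way
#' and downsampled at the scan times.
#'
#' @param spec a [dcm_spec()].
#' @param design a [design_spec()] whose input count matches the spec.
#' @param theta optional free-parameter vector (defaults to the prior mean).
#' @return an object of class `state_path` with `states` (5 n_regions rows by
#'   T columns), `bold_micro` (microtime BOLD), `bold` (n_regions by n_scans)
#'   and `times`.
#' @export
integrate_dcm <- function(spec, design, theta = NULL) {
  stopifnot(inherits(spec, "dcm_spec"), inherits(design, "design_spec"))
  if (design$n_inputs != spec$n_inputs)
    stop(sprintf("design has %d input(s), model expects %d",
                 design$n_inputs, spec$n_inputs), call. = FALSE)
  if (!is.null(theta)) spec <- dcm_apply_theta(spec, theta)
  n <- spec$n_regions
  Bcube <- array(unlist(spec$B), dim = c(n, n, max(1L, spec$n_inputs)))
  hasB <- any(Bcube != 0)
  if (is.null(spec$D)) {
    Dcube <- array(0, dim = c(n, n, 1L)); hasD <- FALSE
  } else {
    Dcube <- array(unlist(spec$D), dim = c(n, n, n))
    hasD <- any(Dcube != 0)
  }
  out <- .dcm_rk4_cpp(spec$A, Bcube, spec$C, Dcube, hasB, hasD,
                      design$inputs, design$dt,
                      spec$hemo$kappa, spec$hemo$gamma, spec$hemo$tau,
                      spec$hemo$alpha, spec$hemo$E0, spec$hemo$V0,
                      spec$obs_gain, 1e6)
  if (out$bad_t >= 0) {
    th <- if (is.null(theta)) dcm_prior_mean(spec) else theta
    stop(sprintf("DCM integration diverged at t = %.2f s (|state| > 1e6); parameters: %s",
                 out$bad_t * design$dt,
                 paste(sprintf("%s=%.3g", dcm_param_names(spec), th),
                       collapse = ", ")), call. = FALSE)
  }
  structure(list(states = out$states, bold_micro = out$bold,
                 bold = out$bold[, design$sample_idx, drop = FALSE],
                 times = design$times, sample_idx = design$sample_idx,
                 n_regions = n),
            class = "state_path")
}

#' @export
print.state_path <- function(x, ...) {
  cat(sprintf("<state_path: %d regions x %d microtime points, %d scans>\n",
              x$n_regions, ncol(x$states), ncol(x$bold)))
  invisible(x)
}

#' Compile a DCM into a nonlinear Gaussian generative model
#'
#' The observation mapping sends the free-parameter vector to the stacked
#' BOLD time series at scan times (region-major: all scans of region 1, then
#' region 2, ...). Free parameters carry independent Gaussian shrinkage
#' priors centred on the specification's values (neural) or 0 (hemodynamic
#' and observation log-multipliers); the residual precision carries a Gamma
#' hyperprior.
#'
#' @param spec a [dcm_spec()] with a non-empty free mask.
#' @param design optional [design_spec()] used to fix and validate `n_y`.
#' @param priors list with entries `neural_sd`, `hemo_sd`, `obs_sd`
#'   (prior standard deviations, default 1 each) and `precision` =
#'   `c(shape, scale)` of the Gamma noise-precision prior (default
#'   `c(1, 0.1)`).
#' @param name model name.
#' @return an [ng_model()] whose mapping takes `(theta, design)`.
#' @export
dcm_as_ng_model <- function(spec, design = NULL, priors = list(),
                            name = "dcm") {
  stopifnot(inherits(spec, "dcm_spec"))
  pr <- utils::modifyList(list(neural_sd = 1, hemo_sd = 1, obs_sd = 1,
                               precision = c(shape = 1, scale = 0.1)),
                          priors)
  eta <- dcm_prior_mean(spec)
  f <- spec$free
  n_neural <- sum(f$A) + sum(vapply(f$B, sum, numeric(1))) + sum(f$C) +
    if (!is.null(f$D)) sum(vapply(f$D, sum, numeric(1))) else 0L
  n_hemo <- sum(f$hemo_decay) + sum(f$hemo_transit)
  n_obs <- sum(f$obs_gain)
  sds <- c(rep(pr$neural_sd, n_neural), rep(pr$hemo_sd, n_hemo),
           rep(pr$obs_sd, n_obs))
  mapping <- function(theta, design) {
    path <- integrate_dcm(spec, design, theta = theta)
    as.numeric(t(path$bold))
  }
  m <- ng_model(name, mapping, prior_mean = eta, prior_cov = sds^2,
                noise_precision_prior = pr$precision,
                n_y = if (is.null(design)) NULL else
                  spec$n_regions * design$n_scans)
  m$dcm_spec <- spec
  m
}

#' Simulate a BOLD dataset from a DCM
#'
#' Deterministic forward BOLD plus i.i.d. Gaussian noise of the given
#' precision; fully reproducible from the seed.
#'
#' @param spec a [dcm_spec()].
#' @param design a [design_spec()].
#' @param theta `"prior-mean"` (default), `"sampled"` (free parameters drawn
#'   from a standard-deviation-1 shrinkage prior around the prior mean), or a
#'   numeric free-parameter vector.
#' @param noise_precision residual precision (> 0); `Inf` gives noiseless
#'   data.
#' @param seed integer seed.
#' @param prior_sd prior standard deviation used when `theta = "sampled"`.
#' @return an object of class `dcm_dataset` with `y` (n_regions x n_scans,
#'   percent signal change), `TR`, `noise_precision`, `seed`, `theta` and the
#'   generating design.
#' @export
simulate_dataset <- function(spec, design, theta = "prior-mean",
                             noise_precision, seed = 1, prior_sd = 1) {
  if (!is.numeric(noise_precision) || noise_precision <= 0)
    stop("noise_precision must be > 0", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  eta <- dcm_prior_mean(spec)
  th <- if (is.numeric(theta)) theta
        else if (identical(theta, "prior-mean")) eta
        else if (identical(theta, "sampled")) eta + rnorm(length(eta),
                                                          0, prior_sd)
        else stop("theta must be 'prior-mean', 'sampled' or a numeric vector",
                  call. = FALSE)
  path <- integrate_dcm(spec, design, theta = th)
  y <- path$bold
  if (is.finite(noise_precision))
    y <- y + matrix(rnorm(length(y), 0, 1 / sqrt(noise_precision)),
                    nrow(y), ncol(y))
  structure(list(y = y, TR = design$TR, noise_precision = noise_precision,
                 seed = seed, theta = th, design = design,
                 n_regions = nrow(y), n_scans = ncol(y)),
            class = "dcm_dataset")
}

#' @export
print.dcm_dataset <- function(x, ...) {
  cat(sprintf("<dcm_dataset: %d regions x %d scans, TR = %g s, precision = %g, seed = %d>\n",
              x$n_regions, x$n_scans, x$TR, x$noise_precision, x$seed))
  invisible(x)
}

## stack a dataset the way the DCM observation mapping stacks its output
flatten_dataset <- function(data) {
  if (inherits(data, "dcm_dataset")) as.numeric(t(data$y))
  else as.numeric(data)
}
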