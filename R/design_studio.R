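## Design generators, the scenario library, risk-vs-design curves,
## Monte-Carlo validation of the bounds, and the data-splitting analysis.

## deterministic sub-seed derivation (kept below 2^31)
mix_seed <- function(seed, ...) {
  ix <- c(seed, ...)
  s <- 0
  for (v in ix) s <- (s * 1000003 + (v %% 65521) + 1) %% 2147480000
  as.integer(s) + 1L
}

## place binary epochs of the given duration at the given onsets (seconds)
epochs_to_inputs <- function(onsets, epoch, T_, dt) {
  u <- numeric(T_)
  for (o in onsets) {
    i0 <- max(1L, floor(o / dt) + 1L)
    i1 <- min(T_, ceiling((o + epoch) / dt))
    if (i1 >= i0) u[i0:i1] <- 1
  }
  u
}

#' Blocked on/off (square-wave) design
#'
#' Binary square-wave inputs: epochs of the given duration placed at a mean
#' inter-block interval, with truncated-Gaussian jitter added to each onset
#' (truncation keeps epochs non-overlapping and inside the session). With
#' more than one input, blocks cycle through all non-null factorial input
#' combinations, balanced in their number of repetitions and permuted by the
#' seed.
#'
#' @param epoch_duration "on" duration in seconds (< session_length).
#' @param session_length session duration in seconds (default 300 s).
#' @param inter_block_interval mean onset-to-onset interval in seconds
#'   (default twice the epoch duration, i.e. a 50 percent duty cycle).
#' @param jitter_sd onset jitter standard deviation in seconds (default 2 s).
#' @param seed integer seed.
#' @param n_inputs number of input channels.
#' @param dt microtime step (default 0.1 s).
#' @param TR scan interval (default 1.3 s).
#' @return a [design_spec()]; annotations record onsets and conditions.
#' @export
make_blocked_design <- function(epoch_duration, session_length = 300,
                                inter_block_interval = 2 * epoch_duration,
                                jitter_sd = 2, seed = 1, n_inputs = 1L,
                                dt = 0.1, TR = 1.3) {
  if (epoch_duration >= session_length)
    stop("epoch_duration must be smaller than session_length", call. = FALSE)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  if (inter_block_interval < epoch_duration)
    stop("infeasible packing: inter_block_interval < epoch_duration",
         call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  T_ <- round(session_length / dt)
  K <- floor(session_length / inter_block_interval)
  if (K < 1L) stop("infeasible packing: no block fits the session",
                   call. = FALSE)
  base <- (seq_len(K) - 1L) * inter_block_interval
  slack <- (inter_block_interval - epoch_duration) / 2
  jit <- if (jitter_sd > 0) pmin(pmax(rnorm(K, 0, jitter_sd), -slack), slack)
         else numeric(K)
  onsets <- pmin(pmax(base + jit, 0), session_length - epoch_duration)
  ## factorial non-null input combinations, balanced then permuted
  if (n_inputs == 1L) {
    conds <- matrix(1, K, 1L)
  } else {
    combos <- as.matrix(expand.grid(rep(list(0:1), n_inputs)))[-1L, ,
                                                               drop = FALSE]
    idx <- rep_len(seq_len(nrow(combos)), K)[sample.int(K)]
    conds <- combos[idx, , drop = FALSE]
  }
  inputs <- matrix(0, n_inputs, T_)
  for (j in seq_len(n_inputs)) {
    on_j <- onsets[conds[, j] == 1]
    if (length(on_j)) inputs[j, ] <- epochs_to_inputs(on_j, epoch_duration,
                                                      T_, dt)
  }
  design_spec(inputs, dt, TR,
              annotations = list(type = "blocked",
                                 epoch_duration = epoch_duration,
                                 inter_block_interval = inter_block_interval,
                                 jitter_sd = jitter_sd, seed = seed,
                                 onsets = onsets, conditions = conds))
}

## pulse-train channel: epochs of brief pulses (for on-line TMS)
pulse_train_channel <- function(onsets, epoch, T_, dt, pulse_hz = 4,
                                pulse_width = 0.1) {
  u <- numeric(T_)
  for (o in onsets) {
    pt <- seq(o, o + epoch - pulse_width, by = 1 / pulse_hz)
    for (p in pt) {
      i0 <- max(1L, floor(p / dt) + 1L)
      i1 <- min(T_, ceiling((p + pulse_width) / dt))
      if (i1 >= i0) u[i0:i1] <- 1
    }
  }
  u
}

#' Event-related design
#'
#' Randomized sequence of brief trials with requested per-type counts and a
#' target mean inter-trial interval (intervals drawn uniformly on 50-150
#' percent of the mean). The blocked variant groups `block_size` consecutive
#' identical trials per block instead of fully randomizing.
#'
#' @param trial_types named list mapping each trial type to the input
#'   channels it activates (e.g. `list(left = 1, right = 2, both = c(1, 2),
#'   null = integer(0))`).
#' @param n_per_type events per type (recycled over types).
#' @param mean_iti target mean inter-trial interval, seconds.
#' @param seed integer seed.
#' @param dt,TR microtime step and scan interval, seconds.
#' @param blocked group consecutive identical trials into blocks?
#' @param block_size trials per block for the blocked variant.
#' @param event_duration stimulus duration per event, seconds.
#' @return a [design_spec()]; annotations record the trial sequence, onsets
#'   and realized mean ITI.
#' @export
make_event_design <- function(trial_types, n_per_type, mean_iti = 2,
                              seed = 1, dt = 0.1, TR = 1.3, blocked = FALSE,
                              block_size = 10L, event_duration = 0.5) {
  stopifnot(is.list(trial_types), length(trial_types) >= 1L)
  if (mean_iti <= 0) stop("mean_iti must be > 0", call. = FALSE)
  n_per_type <- rep_len(n_per_type, length(trial_types))
  if (any(n_per_type < 1L)) stop("counts must be positive", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  types <- rep(names(trial_types), n_per_type)
  if (blocked) {
    blocks <- unlist(lapply(seq_along(trial_types), function(k) {
      nb <- ceiling(n_per_type[k] / block_size)
      rep(names(trial_types)[k], nb)
    }))
    blocks <- sample(blocks)
    seq_types <- unlist(lapply(blocks, rep, times = block_size))
    ## trim over-filled types back to the requested counts
    keep <- unlist(lapply(names(trial_types), function(tt) {
      which(seq_types == tt)[seq_len(min(sum(seq_types == tt),
        n_per_type[match(tt, names(trial_types))]))]
    }))
    seq_types <- seq_types[sort(keep)]
  } else {
    seq_types <- sample(types)
  }
  n_ev <- length(seq_types)
  itis <- runif(n_ev, 0.5 * mean_iti, 1.5 * mean_iti)
  onsets <- cumsum(c(0, itis[-n_ev]))
  session <- onsets[n_ev] + itis[n_ev] + 16   # tail for the hemodynamic decay
  T_ <- round(session / dt)
  n_chan <- max(c(1L, unlist(trial_types)))
  inputs <- matrix(0, n_chan, T_)
  for (e in seq_len(n_ev)) {
    ch <- trial_types[[seq_types[e]]]
    for (j in ch) {
      i0 <- max(1L, floor(onsets[e] / dt) + 1L)
      i1 <- min(T_, ceiling((onsets[e] + event_duration) / dt))
      inputs[j, i0:i1] <- 1
    }
  }
  design_spec(inputs, dt, TR,
              annotations = list(type = if (blocked) "event-blocked"
                                        else "event-related",
                                 sequence = seq_types, onsets = onsets,
                                 n_events = n_ev,
                                 mean_iti = mean(itis), target_iti = mean_iti,
                                 seed = seed))
}

#' Pairs of input sequences with controlled temporal correlation
#'
#' Builds, for each requested correlation level, a two-channel blocked design
#' in which the second channel is a time-shifted copy of the first; the shift
#' is chosen (analytically for a 50 percent duty cycle, then refined
#' numerically) so that the empirical correlation of the two binary
#' microtime sequences matches the requested level within 0.05.
#'
#' @param correlation_levels numeric vector of target correlations in
#'   `[0, 1)`.
#' @param epoch_duration,session_length,inter_block_interval,jitter_sd,seed,dt,TR
#'   blocked-design parameters, see [make_blocked_design()].
#' @return list of two-input [design_spec()] objects; each records its
#'   target and realized correlation in `annotations`.
#' @export
make_correlated_pair_designs <- function(correlation_levels,
                                         epoch_duration = 16,
                                         session_length = 300,
                                         inter_block_interval = 32,
                                         jitter_sd = 2, seed = 1,
                                         dt = 0.1, TR = 1.3) {
  if (any(correlation_levels < 0 | correlation_levels >= 1))
    stop("correlation levels must lie in [0, 1)", call. = FALSE)
  base <- make_blocked_design(epoch_duration, session_length,
                              inter_block_interval, jitter_sd, seed,
                              n_inputs = 1L, dt = dt, TR = TR)
  u1 <- base$inputs[1, ]
  T_ <- length(u1)
  onsets <- base$annotations$onsets
  shifted <- function(s) {
    u2 <- epochs_to_inputs(pmin(onsets + s, session_length - epoch_duration),
                           epoch_duration, T_, dt)
    u2
  }
  p <- epoch_duration / inter_block_interval
  lapply(correlation_levels, function(lv) {
    s0 <- epoch_duration - inter_block_interval * (lv * p * (1 - p) + p^2)
    grid <- seq(max(0, s0 - 4), min(inter_block_interval - 1e-9, s0 + 4),
                by = dt)
    cors <- vapply(grid, function(s) stats::cor(u1, shifted(s)), numeric(1))
    s_best <- grid[which.min(abs(cors - lv))]
    u2 <- shifted(s_best)
    got <- stats::cor(u1, u2)
    if (abs(got - lv) > 0.05)
      stop(sprintf("cannot attain correlation %.2f under the packing constraints (best %.3f)",
                   lv, got), call. = FALSE)
    design_spec(rbind(u1, u2), dt, TR,
                annotations = list(type = "correlated-pair",
                                   target_correlation = lv,
                                   realized_correlation = got,
                                   shift = s_best, seed = seed,
                                   epoch_duration = epoch_duration))
  })
}

## ---- scenario library ----------------------------------------------------

## two-region spec builder; `free` entries are given as index matrices
two_region <- function(A, B = NULL, C, D = NULL, free_neural,
                       free_hemo = TRUE, free_obs = TRUE) {
  n <- 2L
  fm <- free_mask_empty(n, ncol(C), !is.null(D))
  for (e in free_neural) {
    what <- e[[1]]
    if (what == "A") fm$A[e[[2]], e[[3]]] <- TRUE
    else if (what == "C") fm$C[e[[2]], e[[3]]] <- TRUE
    else if (what == "B") fm$B[[e[[4]]]][e[[2]], e[[3]]] <- TRUE
    else if (what == "D") fm$D[[e[[4]]]][e[[2]], e[[3]]] <- TRUE
  }
  fm$hemo_decay[] <- free_hemo
  fm$hemo_transit[] <- free_hemo
  fm$obs_gain[] <- free_obs
  dcm_spec(A, B, C, D, free = fm)
}

A0 <- function(a12 = 0, a21 = 0) matrix(c(-1, a21, a12, -1), 2L, 2L)

#' Scenario library of canonical network-identification questions
#'
#' Fully specified, seeded comparison-set builders and design generators for
#' the canonical two-region questions (where a driving input enters; whether
#' a connection is modulated; whether a feedback connection exists), the
#' matched-input pair used for Monte-Carlo bound validation, the 3x2
#' factorial psycho-physiological-interaction (PPI) set with its two family
#' partitions, the TMS-site variant, and the bimanual finger-tapping set.
#'
#' Each scenario provides `build(eta, precision)` returning a [model_set()]
#' (`eta` is the prior mean of the distinctive neural couplings, `precision`
#' the Gamma noise-precision prior scale), `make_design(...)` returning a
#' [design_spec()], grids `etas`/`epochs`, and family `partitions` where
#' applicable.
#'
#' @param name one of `"input-entry-pair"`, `"driving-input"`,
#'   `"modulatory-input"`, `"feedback"`, `"ppi-3x2"`, `"tms-site"`,
#'   `"finger-tapping"`.
#' @return an object of class `bms_scenario`.
#' @export
scenario_library <- function(name) {
  known <- c("input-entry-pair", "driving-input", "modulatory-input",
             "feedback", "ppi-3x2", "tms-site", "finger-tapping")
  if (!name %in% known)
    stop(sprintf("unknown scenario '%s'; available: %s", name,
                 paste(known, collapse = ", ")), call. = FALSE)
  prset <- function(precision) list(precision = c(shape = 1,
                                                  scale = precision))
  sc <- switch(
    name,
    "input-entry-pair" = list(
      build = function(eta = 0.4, precision = 1) {
        m1 <- two_region(A0(eta, eta), C = diag(2),
                         free_neural = list(list("A", 1, 2), list("A", 2, 1),
                                            list("C", 1, 1), list("C", 2, 2)))
        m2 <- two_region(A0(eta, eta), C = matrix(c(0, 1, 1, 0), 2),
                         free_neural = list(list("A", 1, 2), list("A", 2, 1),
                                            list("C", 2, 1), list("C", 1, 2)))
        model_set(list(dcm_as_ng_model(m1, priors = prset(precision),
                                       name = "u1>r1,u2>r2"),
                       dcm_as_ng_model(m2, priors = prset(precision),
                                       name = "u1>r2,u2>r1")))
      },
      specs = function(eta = 0.4) list(
        two_region(A0(eta, eta), C = diag(2),
                   free_neural = list(list("A", 1, 2), list("A", 2, 1),
                                      list("C", 1, 1), list("C", 2, 2))),
        two_region(A0(eta, eta), C = matrix(c(0, 1, 1, 0), 2),
                   free_neural = list(list("A", 1, 2), list("A", 2, 1),
                                      list("C", 2, 1), list("C", 1, 2)))),
      make_design = function(correlation = 0, seed = 1, epoch_duration = 16)
        make_correlated_pair_designs(correlation, epoch_duration,
                                     seed = seed)[[1]],
      correlation_levels = c(0, 0.5, 0.9), etas = c(0.2, 0.6),
      noise_precisions = c(0.1, 0.3)),
    "driving-input" = list(
      build = function(eta = 0.4, precision = 0.1) {
        mk <- function(Cm, nm)
          dcm_as_ng_model(two_region(A0(eta, eta), C = Cm,
                                     free_neural = list(
                                       list("A", 1, 2), list("A", 2, 1),
                                       list("C", which(Cm != 0), 1))),
                          priors = prset(precision), name = nm)
        model_set(list(mk(matrix(c(1, 0), 2), "drive-r1"),
                       mk(matrix(c(0, 1), 2), "drive-r2")))
      },
      make_design = function(epoch_duration = 16, seed = 1)
        make_blocked_design(epoch_duration, inter_block_interval = 40,
                            seed = seed),
      epochs = c(4, 8, 16, 24, 32), etas = c(0.2, 0.6)),
    "modulatory-input" = list(
      build = function(eta = 0.4, precision = 0.1) {
        Cm <- matrix(c(1, 0, 0, 0), 2)
        m1 <- two_region(A0(0, eta),
                         B = list(matrix(0, 2, 2),
                                  matrix(c(0, eta, 0, 0), 2)),
                         C = Cm,
                         free_neural = list(list("A", 2, 1),
                                            list("C", 1, 1),
                                            list("B", 2, 1, 2)))
        m2 <- two_region(A0(0, eta), C = Cm,
                         free_neural = list(list("A", 2, 1),
                                            list("C", 1, 1)))
        model_set(list(dcm_as_ng_model(m1, priors = prset(precision),
                                       name = "mod+"),
                       dcm_as_ng_model(m2, priors = prset(precision),
                                       name = "mod-")))
      },
      make_design = function(epoch_duration = 16, seed = 1)
        make_blocked_design(epoch_duration, inter_block_interval = 40,
                            n_inputs = 2L, seed = seed),
      epochs = c(4, 8, 16, 24, 32), etas = c(0.2, 0.6)),
    "feedback" = list(
      build = function(eta = 0.4, precision = 0.1) {
        Cm <- matrix(c(1, 0), 2)
        m1 <- two_region(A0(eta, eta), C = Cm,
                         free_neural = list(list("A", 2, 1), list("A", 1, 2),
                                            list("C", 1, 1)))
        m2 <- two_region(A0(0, eta), C = Cm,
                         free_neural = list(list("A", 2, 1),
                                            list("C", 1, 1)))
        model_set(list(dcm_as_ng_model(m1, priors = prset(precision),
                                       name = "fbk+"),
                       dcm_as_ng_model(m2, priors = prset(precision),
                                       name = "fbk-")))
      },
      make_design = function(epoch_duration = 16, seed = 1)
        make_blocked_design(epoch_duration, inter_block_interval = 40,
                            seed = seed),
      epochs = c(4, 8, 16, 24, 32), etas = c(0.2, 0.6)),
    "ppi-3x2" = list(
      build = function(eta = 0.4, precision = 0.1, tms_site = 0L,
                       tms_eta = 0.1) {
        ppi_model_set(eta, precision, tms_site, tms_eta)
      },
      make_design = function(epoch_duration = 16, seed = 1)
        make_blocked_design(epoch_duration, inter_block_interval = 40,
                            n_inputs = 2L, seed = seed),
      epochs = c(4, 8, 16, 24, 32), etas = c(0.2, 0.6),
      partitions = list(
        interpretation = c("psi-mod", "r1-mod", "r1-mod",
                           "psi-mod", "r1-mod", "r1-mod"),
        feedback = c("fbk-", "fbk-", "fbk-", "fbk+", "fbk+", "fbk+"))),
    "tms-site" = list(
      build = function(eta = 0.4, precision = 0.1, tms_site = 0L,
                       tms_eta = 0.1) {
        ppi_model_set(eta, precision, tms_site, tms_eta,
                      with_tms_channel = TRUE)
      },
      make_design = function(tms_site = 0L, seed = 1, epoch_duration = 16,
                             tms_epoch = 8) {
        d <- make_blocked_design(epoch_duration, n_inputs = 2L, seed = seed)
        T_ <- d$n_time
        old <- .Random.seed_save()
        on.exit(.Random.seed_restore(old), add = TRUE)
        set.seed(mix_seed(seed, tms_site + 1L))
        if (tms_site > 0L) {
          K <- floor(300 / (2 * tms_epoch))
          base <- (seq_len(K) - 1L) * 2 * tms_epoch + tms_epoch / 2
          jit <- pmin(pmax(rnorm(K, 0, 2), -tms_epoch / 2), tms_epoch / 2)
          tms <- pulse_train_channel(pmin(pmax(base + jit, 0),
                                          300 - tms_epoch),
                                     tms_epoch, T_, d$dt)
        } else tms <- numeric(T_)
        design_spec(rbind(d$inputs, tms), d$dt, d$TR,
                    annotations = c(d$annotations,
                                    list(tms_site = tms_site)))
      },
      etas = c(0.2, 0.6),
      partitions = list(
        interpretation = c("psi-mod", "r1-mod", "r1-mod",
                           "psi-mod", "r1-mod", "r1-mod"),
        feedback = c("fbk-", "fbk-", "fbk-", "fbk+", "fbk+", "fbk+"))),
    "finger-tapping" = list(
      build = function(eta = 0.4, precision = 0.05) {
        mk <- function(Cm, fbk, nm, cfree) {
          fn <- c(if (fbk) list(list("A", 1, 2), list("A", 2, 1)),
                  cfree)
          dcm_as_ng_model(two_region(A0(if (fbk) eta else 0,
                                        if (fbk) eta else 0), C = Cm,
                                     free_neural = fn),
                          priors = prset(precision), name = nm)
        }
        F_  <- mk(matrix(c(0, 1, 1, 0), 2), TRUE, "F",
                  list(list("C", 2, 1), list("C", 1, 2)))
        IF_ <- mk(diag(2), TRUE, "IF",
                  list(list("C", 1, 1), list("C", 2, 2)))
        NF_ <- mk(matrix(c(0, 1, 1, 0), 2), FALSE, "NF",
                  list(list("C", 2, 1), list("C", 1, 2)))
        NF2 <- mk(matrix(1, 2, 2), FALSE, "NF2",
                  list(list("C", 1, 1), list("C", 2, 1),
                       list("C", 1, 2), list("C", 2, 2)))
        model_set(list(F_, IF_, NF_, NF2),
                  family_labels = c("family1", "family2",
                                    "family1", "family2"))
      },
      trial_types = list(left = 1L, right = 2L, both = c(1L, 2L),
                         null = integer(0)),
      make_design = function(blocked = FALSE, n_per_type = 100L, seed = 1)
        make_event_design(list(left = 1L, right = 2L, both = c(1L, 2L),
                               null = integer(0)),
                          n_per_type = n_per_type, mean_iti = 2,
                          seed = seed, blocked = blocked),
      etas = c(0.2, 0.6)))
  structure(c(list(name = name), sc), class = "bms_scenario")
}

## the 3x2 factorial PPI comparison set (reconstructed structures):
## inputs: u1 = stimulus driving region 1, u2 = psychological factor psi,
## optional u3 = TMS pulse train entering region `tms_site`.
## Interpretation classes: mA: psi modulates the 1->2 connection;
## mB: psi drives region 2 directly; mC: psi modulates region 2's
## self-connection (gain). Second factor: with/without feedback 2->1.
ppi_model_set <- function(eta, precision, tms_site = 0L, tms_eta = 0.1,
                          with_tms_channel = tms_site > 0L) {
  n_in <- if (with_tms_channel) 3L else 2L
  mk <- function(class, fbk) {
    Cm <- matrix(0, 2, n_in); Cm[1, 1] <- 1
    B <- replicate(n_in, matrix(0, 2, 2), simplify = FALSE)
    fn <- list(list("A", 2, 1), list("C", 1, 1))
    if (class == "A") { B[[2]][2, 1] <- eta; fn <- c(fn, list(list("B", 2, 1, 2))) }
    if (class == "B") { Cm[2, 2] <- eta; fn <- c(fn, list(list("C", 2, 2))) }
    if (class == "C") { B[[2]][2, 2] <- eta; fn <- c(fn, list(list("B", 2, 2, 2))) }
    if (fbk) fn <- c(fn, list(list("A", 1, 2)))
    if (tms_site > 0L) {
      Cm[tms_site, 3] <- tms_eta
      fn <- c(fn, list(list("C", tms_site, 3)))
    }
    A <- A0(if (fbk) eta else 0, eta)
    dcm_as_ng_model(
      two_region(A, B = B, C = Cm, free_neural = fn),
      priors = list(precision = c(shape = 1, scale = precision)),
      name = sprintf("m%s%s", class, if (fbk) "+" else "-"))
  }
  model_set(list(mk("A", FALSE), mk("B", FALSE), mk("C", FALSE),
                 mk("A", TRUE), mk("B", TRUE), mk("C", TRUE)),
            family_labels = c("fbk-", "fbk-", "fbk-",
                              "fbk+", "fbk+", "fbk+"))
}

#' @export
print.bms_scenario <- function(x, ...) {
  cat(sprintf("<bms_scenario '%s'>\n", x$name))
  invisible(x)
}

## ---- risk curves and Monte-Carlo validation ------------------------------

#' Average Laplace-Chernoff risk across a design/prior grid
#'
#' For every (design grid point, coupling prior mean) pair, draws jittered
#' designs and aggregates the Laplace-Chernoff risk (or family risk when a
#' partition is requested). Deterministic given the seed.
#'
#' @param scenario a [scenario_library()] scenario.
#' @param epochs epoch-duration grid (defaults to the scenario's).
#' @param etas coupling prior-mean grid (defaults to the scenario's).
#' @param n_jitter_draws jittered designs per grid point.
#' @param seed integer seed.
#' @param partition optional name or labels of a family partition.
#' @param precision Gamma precision-prior scale forwarded to the builder.
#' @return data frame with columns `epoch`, `eta`, `mean_risk`, `sd_risk`,
#'   `n_draws`.
#' @export
risk_curve <- function(scenario, epochs = NULL, etas = NULL,
                       n_jitter_draws = 8L, seed = 1, partition = NULL,
                       precision = 0.1) {
  stopifnot(inherits(scenario, "bms_scenario"))
  if (is.null(epochs)) epochs <- scenario$epochs
  if (is.null(etas)) etas <- scenario$etas
  if (!length(epochs) || !length(etas))
    stop("empty design or prior grid", call. = FALSE)
  labels <- NULL
  rows <- list()
  for (ei in seq_along(epochs)) for (hi in seq_along(etas)) {
    ms <- scenario$build(etas[hi], precision = precision)
    if (!is.null(partition)) {
      labels <- if (is.character(partition) && length(partition) == 1L)
        scenario$partitions[[partition]] else partition
      if (is.null(labels))
        stop(sprintf("unknown partition for grid point (epoch %g, eta %g)",
                     epochs[ei], etas[hi]), call. = FALSE)
    }
    risks <- vapply(seq_len(n_jitter_draws), function(d) {
      dsg <- scenario$make_design(epochs[ei],
                                  seed = mix_seed(seed, ei, hi, d))
      r <- suppressWarnings(
        if (is.null(labels)) laplace_chernoff_risk(ms, dsg)
        else family_risk(ms, labels, dsg))
      r$laplace_chernoff_risk
    }, numeric(1))
    rows[[length(rows) + 1L]] <-
      data.frame(epoch = epochs[ei], eta = etas[hi],
                 mean_risk = mean(risks), sd_risk = stats::sd(risks),
                 n_draws = n_jitter_draws)
  }
  do.call(rbind, rows)
}

#' Monte-Carlo estimate of the model selection error rate
#'
#' For every cell of the factor grid (generating model x coupling level x
#' noise precision), simulates `n_noise_reps` datasets at the generating
#' model's prior mean with fresh residual draws, inverts every model in the
#' comparison set by variational Laplace, selects the maximum-posterior
#' model, and counts mismatches with the simulated ground truth. Inversion
#' failures are counted and reported separately, never silently dropped.
#'
#' @param scenario a [scenario_library()] scenario whose `specs(eta)` method
#'   provides the generating [dcm_spec()]s.
#' @param design a [design_spec()].
#' @param coupling_levels coupling prior-mean factor levels.
#' @param noise_precisions residual-precision factor levels.
#' @param n_noise_reps residual realisations per cell (default 8).
#' @param seed integer seed.
#' @param config inversion configuration, see [invert_vl()].
#' @return an object of class `mc_result`: overall `error_rate` with
#'   binomial `sd`, a per-cell data frame `cells`, a per-precision summary
#'   `by_precision`, and `n_failures`.
#' @export
monte_carlo_error_rate <- function(scenario, design, coupling_levels,
                                   noise_precisions, n_noise_reps = 8L,
                                   seed = 1, config = list()) {
  stopifnot(inherits(scenario, "bms_scenario"),
            inherits(design, "design_spec"))
  cells <- list()
  n_fail <- 0L
  for (cl in coupling_levels) for (np in noise_precisions) {
    ms <- scenario$build(cl, precision = np)
    specs <- if (!is.null(scenario$specs)) scenario$specs(cl)
             else lapply(ms$models, function(m) m$dcm_spec)
    M <- length(ms$models)
    for (gm in seq_len(M)) {
      errs <- 0L; trials <- 0L; pes <- numeric(0)
      for (r in seq_len(n_noise_reps)) {
        ds <- simulate_dataset(specs[[gm]], design, theta = "prior-mean",
                               noise_precision = np,
                               seed = mix_seed(seed, which(
                                 coupling_levels == cl),
                                 which(noise_precisions == np), gm, r))
        Fs <- rep(NA_real_, M)
        for (mi in seq_len(M)) {
          fit <- tryCatch(invert_vl(ms$models[[mi]], ds, design = design,
                                    config = config),
                          error = function(e) NULL)
          if (is.null(fit)) { n_fail <- n_fail + 1L } else
            Fs[mi] <- fit$free_energy
        }
        if (any(is.na(Fs))) next
        mp <- model_posterior(Fs, ms$model_priors)
        trials <- trials + 1L
        if (mp$selected != gm) errs <- errs + 1L
        ## objective probability that this very selection is wrong: a
        ## finer-grained estimator of the error rate than the 0/1 count
        pes <- c(pes, posterior_error_probability(mp$posterior))
      }
      cells[[length(cells) + 1L]] <-
        data.frame(coupling = cl, precision = np, gen_model = gm,
                   errors = errs, trials = trials,
                   rate = if (trials) errs / trials else NA_real_,
                   mean_post_error = if (trials) mean(pes) else NA_real_)
    }
  }
  cells <- do.call(rbind, cells)
  n <- sum(cells$trials); k <- sum(cells$errors)
  p <- if (n) k / n else NA_real_
  by_prec <- do.call(rbind, lapply(split(cells, cells$precision),
    function(d) {
      nn <- sum(d$trials); kk <- sum(d$errors)
      data.frame(precision = d$precision[1], trials = nn, errors = kk,
                 rate = kk / nn, sd = sqrt(kk / nn * (1 - kk / nn) / nn),
                 mean_post_error = sum(d$mean_post_error * d$trials) / nn)
    }))
  structure(list(n_trials = n, n_errors = k, error_rate = p,
                 sd = if (n) sqrt(p * (1 - p) / n) else NA_real_,
                 cells = cells, by_precision = by_prec,
                 n_failures = n_fail, seed = seed),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result: %d/%d errors (rate %.3f +- %.3f), %d inversion failure(s)>\n",
              x$n_errors, x$n_trials, x$error_rate, x$sd, x$n_failures))
  invisible(x)
}

#' Data-splitting analysis of selection reliability
#'
#' Splits a session (data and stimulation sequence) into consecutive
#' segments, inverts the full comparison set on each segment independently,
#' and averages the posterior probability of selecting wrongly across
#' segments; this approximates the selection error rate at the reduced
#' effective sample size. The Laplace-Chernoff risk is also recomputed per
#' segment.
#'
#' @param dataset a `dcm_dataset`.
#' @param design the generating [design_spec()].
#' @param model_set a [model_set()].
#' @param n_splits number of consecutive segments (must leave at least
#'   `min_scans` scans per segment).
#' @param truth index of the true model, or (with families) the true family
#'   label; used to score the error probability. `NULL` scores
#'   `1 - max(posterior)` instead.
#' @param families optional family labels; selection and error probability
#'   are then computed at the family level.
#' @param config inversion configuration.
#' @param min_scans minimum scans per segment (default 20).
#' @return list with `per_segment` (data frame of selections and error
#'   probabilities), `avg_error_prob`, `mean_risk`, `n_splits`.
#' @export
split_analysis <- function(dataset, design, model_set, n_splits = 1L,
                           truth = NULL, families = NULL, config = list(),
                           min_scans = 20L) {
  stopifnot(inherits(dataset, "dcm_dataset"), inherits(design, "design_spec"),
            inherits(model_set, "model_set"))
  S <- dataset$n_scans
  if (floor(S / n_splits) < min_scans)
    stop(sprintf("segments too short for inversion: %d scans split %d ways",
                 S, n_splits), call. = FALSE)
  if (is.null(families)) families <- model_set$family_labels
  bounds <- floor(seq(0, S, length.out = n_splits + 1L))
  rows <- list(); risks <- numeric(0)
  for (s in seq_len(n_splits)) {
    sc_idx <- (bounds[s] + 1L):bounds[s + 1L]
    t0 <- if (s == 1L) 0L else design$sample_idx[bounds[s]]
    t1 <- design$sample_idx[bounds[s + 1L]]
    d_seg <- design_spec(design$inputs[, (t0 + 1L):t1, drop = FALSE],
                         design$dt, design$TR,
                         sample_idx = design$sample_idx[sc_idx] - t0)
    y_seg <- dataset$y[, sc_idx, drop = FALSE]
    Fs <- vapply(model_set$models, function(m)
      invert_vl(m, as.numeric(t(y_seg)), design = d_seg,
                config = config)$free_energy, numeric(1))
    mp <- model_posterior(Fs, model_set$model_priors)
    if (!is.null(families)) {
      fam_names <- unique(families)
      fam_post <- vapply(fam_names, function(f)
        sum(mp$posterior[families == f]), numeric(1))
      sel <- fam_names[which.max(fam_post)]
      ep <- if (is.null(truth)) 1 - max(fam_post)
            else 1 - fam_post[match(truth, fam_names)]
      rk <- suppressWarnings(
        family_risk(model_set, families, d_seg)$laplace_chernoff_risk)
    } else {
      sel <- mp$selected
      ep <- if (is.null(truth)) 1 - max(mp$posterior)
            else 1 - mp$posterior[truth]
      rk <- suppressWarnings(
        laplace_chernoff_risk(model_set, d_seg)$laplace_chernoff_risk)
    }
    risks <- c(risks, rk)
    rows[[s]] <- data.frame(segment = s, n_scans = length(sc_idx),
                            selected = as.character(sel),
                            error_prob = unname(ep), risk = rk)
  }
  per_segment <- do.call(rbind, rows)
  list(per_segment = per_segment,
       avg_error_prob = mean(per_segment$error_prob),
       mean_risk = mean(risks), n_splits = n_splits)
}
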