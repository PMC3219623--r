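test_that("blocked designs pack, jitter and balance as requested", {
  ## zero jitter: perfectly periodic onsets
  d0 <- make_blocked_design(16, 300, 32, jitter_sd = 0, seed = 1)
  expect_equal(d0$annotations$onsets, seq(0, by = 32, length.out = 9))
  ## block count equals the arithmetic packing, verified by enumeration
  enum <- 0; o <- 0
  while (o + 16 <= 300) { enum <- enum + 1; o <- o + 32 }
  expect_equal(length(d0$annotations$onsets), enum)
  ## binary square wave with the right on-time
  expect_setequal(unique(as.numeric(d0$inputs)), c(0, 1))
  expect_equal(sum(d0$inputs[1, ]) * d0$dt, 9 * 16, tolerance = 2)
  ## jittered onsets stay ordered and non-overlapping
  dj <- make_blocked_design(16, 300, 32, jitter_sd = 2, seed = 2)
  expect_true(all(diff(dj$annotations$onsets) >= 16))
  ## two inputs: factorial conditions balanced within one repetition
  d2 <- make_blocked_design(8, 300, 24, n_inputs = 2L, seed = 3)
  tab <- table(apply(d2$annotations$conditions, 1, paste, collapse = ""))
  expect_equal(length(tab), 3L)          # u1, u2, u1&u2
  expect_lte(diff(range(tab)), 1L)
  expect_error(make_blocked_design(40, 300, 32), "infeasible")
})

test_that("event designs honour counts, ITI and blocking", {
  types <- list(left = 1L, right = 2L, both = c(1L, 2L), null = integer(0))
  ## tiny case: 4 events, permutation by seed
  d4a <- make_event_design(types, 1, seed = 1)
  d4b <- make_event_design(types, 1, seed = 2)
  expect_equal(sort(d4a$annotations$sequence), sort(names(types)))
  expect_false(identical(d4a$annotations$sequence,
                         d4b$annotations$sequence))
  ## the full session: 400 events (100 per type), mean ITI near 2 s
  ft <- scenario_library("finger-tapping")
  de <- ft$make_design(blocked = FALSE, seed = 4)
  expect_equal(de$annotations$n_events, 400L)
  expect_equal(as.integer(table(de$annotations$sequence)), rep(100L, 4))
  ## blocked variant: runs of identical trials in groups of ten
  db <- ft$make_design(blocked = TRUE, seed = 4)
  runs <- rle(db$annotations$sequence)$lengths
  expect_true(all(runs %% 10 == 0))
  expect_equal(as.integer(table(db$annotations$sequence)), rep(100L, 4))
  ## empirical mean ITI over 1e4 events within 2 percent of the target
  dl <- make_event_design(list(a = 1L), n_per_type = 10000, mean_iti = 2,
                          seed = 9)
  expect_equal(dl$annotations$mean_iti, 2, tolerance = 0.02)
})

test_that("correlated input pairs hit their target correlations", {
  ds <- make_correlated_pair_designs(c(0, 0.5, 0.9), seed = 5)
  got <- vapply(ds, function(d) d$annotations$realized_correlation,
                numeric(1))
  expect_lt(abs(got[1]), 0.05)
  expect_true(got[3] >= 0.85 && got[3] <= 0.95)
  expect_equal(got[2], 0.5, tolerance = 0.05)
  expect_error(make_correlated_pair_designs(1.2), "0, 1")
})

test_that("risk increases with the correlation between the two inputs", {
  sc <- scenario_library("input-entry-pair")
  ds <- make_correlated_pair_designs(sc$correlation_levels, seed = 5)
  ms <- sc$build(0.4, precision = 0.1)
  risks <- vapply(ds, function(d) suppressWarnings(
    laplace_chernoff_risk(ms, d))$laplace_chernoff_risk, numeric(1))
  expect_nondecreasing(risks)
  expect_gt(risks[3], risks[1])
})

test_that("risk curves reduce to a direct call and are reproducible", {
  sc <- scenario_library("feedback")
  cc <- risk_curve(sc, epochs = 16, etas = 0.6, n_jitter_draws = 1, seed = 2)
  direct <- suppressWarnings(laplace_chernoff_risk(
    sc$build(0.6, precision = 0.1),
    sc$make_design(16, seed = bmsdesign:::mix_seed(2, 1, 1, 1))))
  expect_equal(cc$mean_risk, direct$laplace_chernoff_risk)
  ## bit-identical reproducibility
  cc2 <- risk_curve(sc, epochs = 16, etas = 0.6, n_jitter_draws = 1,
                    seed = 2)
  expect_identical(cc, cc2)
})

test_that("scenario library exposes the documented comparison sets", {
  expect_error(scenario_library("nope"), "available:")
  for (nm in c("driving-input", "modulatory-input", "feedback")) {
    ms <- scenario_library(nm)$build(0.4)
    expect_length(ms$models, 2L)
  }
  ppi <- scenario_library("ppi-3x2")
  ms6 <- ppi$build(0.4)
  expect_length(ms6$models, 6L)
  expect_length(ppi$partitions, 2L)
  ft <- scenario_library("finger-tapping")
  msf <- ft$build(0.4)
  expect_equal(msf$names, c("F", "IF", "NF", "NF2"))
  expect_equal(msf$family_labels[c(1, 3)], c("family1", "family1"))
  tms <- scenario_library("tms-site")
  d_tms <- tms$make_design(tms_site = 1L, seed = 1)
  expect_equal(d_tms$n_inputs, 3L)
  expect_gt(sum(d_tms$inputs[3, ]), 0)
  d_no <- tms$make_design(tms_site = 0L, seed = 1)
  expect_equal(sum(d_no$inputs[3, ]), 0)
})

test_that("split analysis with one split matches the whole-session analysis", {
  fx <- feedback_fixture(eta = 0.6, seed = 6)
  ds <- simulate_dataset(fx$set$models[[1]]$dcm_spec, fx$design,
                         noise_precision = 0.3, seed = 7)
  whole <- split_analysis(ds, fx$design, fx$set, n_splits = 1L,
                          truth = 1L)
  Fs <- vapply(fx$set$models, function(m)
    invert_vl(m, ds, design = fx$design)$free_energy, numeric(1))
  mp <- model_posterior(Fs)
  expect_equal(whole$per_segment$selected, as.character(mp$selected))
  expect_equal(whole$avg_error_prob, 1 - mp$posterior[1], tolerance = 1e-6)
  expect_error(split_analysis(ds, fx$design, fx$set, n_splits = 50L),
               "too short")
})

test_that("shrinking segments raise the error probability; blocked stays safer", {
  ## synthetic bimanual-task-like session, reduced scale
  ft <- scenario_library("finger-tapping")
  d_blk <- ft$make_design(blocked = TRUE, n_per_type = 25L, seed = 8)
  d_evt <- ft$make_design(blocked = FALSE, n_per_type = 25L, seed = 8)
  ms <- ft$build(0.4, precision = 0.3)
  ds <- simulate_dataset(ms$models[[1]]$dcm_spec, d_blk,
                         noise_precision = 0.3, seed = 9)
  res <- lapply(c(1L, 2L, 4L), function(k)
    split_analysis(ds, d_blk, ms, n_splits = k, truth = "family1",
                   config = list(max_iter = 24)))
  eps <- vapply(res, `[[`, numeric(1), "avg_error_prob")
  expect_nondecreasing(eps, tol = 0.02)
  ## the blocked design is less risky than the event-related one at every
  ## split level (risk recomputed per segment, no inversions needed)
  for (k in c(1L, 2L, 4L)) {
    risk_of <- function(d) {
      S <- d$n_scans
      bounds <- floor(seq(0, S, length.out = k + 1L))
      mean(vapply(seq_len(k), function(s) {
        t0 <- if (s == 1L) 0L else d$sample_idx[bounds[s]]
        t1 <- d$sample_idx[bounds[s + 1L]]
        seg <- design_spec(d$inputs[, (t0 + 1L):t1, drop = FALSE], d$dt,
                           d$TR,
                           sample_idx =
                             d$sample_idx[(bounds[s] + 1L):bounds[s + 1L]] -
                             t0)
        suppressWarnings(family_risk(ms, ms$family_labels,
                                     seg))$laplace_chernoff_risk
      }, numeric(1)))
    }
    expect_lte(risk_of(d_blk), risk_of(d_evt))
  }
})
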