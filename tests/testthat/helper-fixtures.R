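## shared fixtures: everything is built in code, no stored data

g1d <- function(mean, var = 1) gaussian_predictive(mean, var)

## a tiny linear ng_model y = X theta + e
linear_model <- function(X, prior_mean = rep(0, ncol(X)), prior_var = 1,
                         noise_var = 1, name = "linear") {
  ng_model(name, function(th, u) drop(X %*% th), prior_mean = prior_mean,
           prior_cov = prior_var, noise_cov = noise_var, n_y = nrow(X))
}

## short two-region feedback comparison set and design (fast to integrate);
## `set` is the model_set, `set$models` the list of ng_model objects
feedback_fixture <- function(eta = 0.6, epoch = 16, seed = 1,
                             precision = 0.1) {
  sc <- scenario_library("feedback")
  list(scenario = sc, design = sc$make_design(epoch, seed = seed),
       set = sc$build(eta, precision = precision))
}

expect_nondecreasing <- function(x, tol = 0) {
  expect_true(all(diff(x) >= -tol))
}
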