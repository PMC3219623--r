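## Configuration parsing, report serialization and dataset text I/O.

config_schema <- c("scenario", "seed", "output_dir", "verbosity",
                   "epoch_duration", "session_length",
                   "inter_block_interval", "jitter_sd", "n_inputs",
                   "dt", "TR", "eta", "precision", "partition",
                   "correlation_levels", "epochs", "etas",
                   "n_jitter_draws", "noise_precisions", "n_noise_reps",
                   "tol", "max_iter", "model_index", "n_splits")

config_defaults <- list(seed = 1L, verbosity = 1L, epoch_duration = 16,
                        session_length = 300, jitter_sd = 2, dt = 0.1,
                        TR = 1.3, eta = 0.4, precision = 0.1,
                        n_jitter_draws = 8L, n_noise_reps = 8L,
                        tol = 1e-2, max_iter = 64L)

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration, rejects unknown keys (suggesting
#' the nearest known key), and fills defaults.
#'
#' @param path path to a YAML or JSON file.
#' @return validated named list of class `run_config`, with attribute
#'   `"hash"` (md5 of the file) for provenance.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping", call. = FALSE)
  unknown <- setdiff(names(cfg), config_schema)
  if (length(unknown)) {
    hints <- vapply(unknown, function(k) {
      d <- utils::adist(k, config_schema)
      ifelse(min(d) <= 3, sprintf(" (did you mean '%s'?)",
                                  config_schema[which.min(d)]), "")
    }, character(1))
    stop(sprintf("unknown config key(s): %s",
                 paste0(unknown, hints, collapse = ", ")), call. = FALSE)
  }
  cfg <- utils::modifyList(config_defaults, cfg)
  if (is.null(cfg$seed)) stop("a seed is mandatory", call. = FALSE)
  attr(cfg, "hash") <- unname(tools::md5sum(path))
  class(cfg) <- "run_config"
  cfg
}

#' Save a configuration to YAML
#' @param config a named list or `run_config`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  attr(x, "hash") <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

as_report_list <- function(result) {
  if (inherits(result, "risk_report")) {
    list(kind = "risk_report", jsd = result$jsd,
         lower_bound = result$lower_bound,
         upper_bound = result$upper_bound,
         laplace_chernoff_risk = result$laplace_chernoff_risk,
         prior_entropy = result$prior_entropy,
         per_pair_kl = result$per_pair_kl, method = result$method,
         n_models = result$n_models, valid = result$valid)
  } else if (inherits(result, "mc_result")) {
    list(kind = "mc_result", n_trials = result$n_trials,
         n_errors = result$n_errors, error_rate = result$error_rate,
         sd = result$sd, n_failures = result$n_failures,
         seed = result$seed, cells = result$cells,
         by_precision = result$by_precision)
  } else if (inherits(result, "inversion_result")) {
    list(kind = "inversion_result", model = result$model,
         posterior_mean = result$posterior_mean,
         posterior_cov = result$posterior_cov,
         precision_posterior = as.list(result$precision_posterior),
         free_energy = result$free_energy,
         free_energy_trace = result$free_energy_trace,
         converged = result$converged, n_iterations = result$n_iterations)
  } else if (is.data.frame(result) || is.list(result)) {
    c(list(kind = "table"), list(data = result))
  } else stop("unsupported result type", call. = FALSE)
}

#' Write a result report to JSON (and tables to delimited text)
#'
#' Serializes a `risk_report`, `mc_result`, `inversion_result` or plain
#' table to JSON with schema and package version and optional config hash;
#' data-frame members are additionally written as tab-delimited text next
#' to the JSON file.
#'
#' @param result object to serialize.
#' @param path destination `.json` path.
#' @param config optional `run_config` whose hash and seed are embedded.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, config = NULL) {
  rep_ <- as_report_list(result)
  rep_$schema_version <- "1.0"
  rep_$package_version <-
    as.character(utils::packageVersion("bmsdesign"))
  if (!is.null(config)) {
    rep_$config_hash <- attr(config, "hash")
    rep_$seed <- config$seed
  }
  for (nm in names(rep_)) {
    if (is.data.frame(rep_[[nm]])) {
      tab_path <- sub("\\.json$", paste0("_", nm, ".tsv"), path)
      utils::write.table(rep_[[nm]], tab_path, sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  ok <- try(jsonlite::write_json(rep_, path, auto_unbox = TRUE, digits = NA,
                                 pretty = TRUE, na = "null"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop(sprintf("failed to write report to %s: %s", path,
                 attr(ok, "condition")$message), call. = FALSE)
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#' @param path path to the JSON file.
#' @return named list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a simulated dataset as delimited text with a provenance sidecar
#'
#' One column per region (tab-delimited, header `region1..n`), plus a JSON
#' sidecar recording TR, noise precision, seed and parameter vector.
#'
#' @param dataset a `dcm_dataset`.
#' @param path destination `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "dcm_dataset"))
  y <- t(dataset$y)
  colnames(y) <- paste0("region", seq_len(ncol(y)))
  utils::write.table(y, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- sub("\\.[a-zA-Z]+$", ".json", path)
  jsonlite::write_json(list(TR = dataset$TR,
                            noise_precision = dataset$noise_precision,
                            seed = dataset$seed,
                            theta = as.list(dataset$theta)),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#' @param path path to the `.tsv` file.
#' @return a `dcm_dataset` (without the generating design).
#' @export
read_dataset <- function(path) {
  y <- t(as.matrix(utils::read.delim(path)))
  side <- sub("\\.[a-zA-Z]+$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
          else list(TR = NA_real_, noise_precision = NA_real_, seed = NA)
  structure(list(y = unname(y), TR = meta$TR,
                 noise_precision = meta$noise_precision, seed = meta$seed,
                 theta = unlist(meta$theta), design = NULL,
                 n_regions = nrow(y), n_scans = ncol(y)),
            class = "dcm_dataset")
}
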