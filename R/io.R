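#' Read a time-series CSV stream
#'
#' All on-disk streams share one dialect: a `time_s` first column followed by
#' named numeric channels (`emg_bf, emg_rf, emg_vl, emg_vm` for raw EMG;
#' `lmt_<muscle>` and `r_<muscle>` for muscle geometry; `tau_ref` for the
#' reference torque). Missing values are linearly interpolated with a logged
#' count; time must be strictly increasing.
#'
#' @param path CSV file path.
#' @param expected_columns Optional character vector of columns that must be
#'   present; a missing column raises a schema error naming it.
#' @return A tibble.
#' @export
read_timeseries_csv <- function(path, expected_columns = NULL) {
  if (!file.exists(path)) abort_schema(paste("no such file:", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"time_s" %in% names(d)) abort_schema("missing column: time_s")
  if (!is.null(expected_columns)) {
    miss <- setdiff(expected_columns, names(d))
    if (length(miss) > 0) {
      abort_schema(paste("missing column(s):", paste(miss, collapse = ", ")))
    }
  }
  if (any(diff(d$time_s) <= 0)) {
    abort_data(paste("non-monotonic time_s in", path))
  }
  n_na <- sum(is.na(as.matrix(d)))
  if (n_na > 0) {
    inform_log(sprintf("%s: interpolated %d missing value(s)", path, n_na))
    for (ch in setdiff(names(d), "time_s")) {
      if (anyNA(d[[ch]])) {
        d[[ch]] <- stats::approx(d$time_s[!is.na(d[[ch]])],
                                 d[[ch]][!is.na(d[[ch]])],
                                 xout = d$time_s, rule = 2)$y
      }
    }
  }
  tibble::as_tibble(d)
}

#' @rdname read_timeseries_csv
#' @param data Data frame to write.
#' @export
write_timeseries_csv <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(path)
}

# run configuration -----------------------------------------------------------

.config_keys <- c("seed", "out_dir", "analysis_rate", "kpe", "subject",
                  "ga", "sobol", "simplify", "log_level")

#' Default run configuration
#'
#' A nested list validated by [validate_config()]: global `seed`, `out_dir`,
#' `analysis_rate` (Hz), `kpe`, the synthetic `subject` settings (see
#' [synth_config()]), `ga` settings (see [ga_config()]), `sobol` settings
#' (`samples`, `sequence`) and `simplify` settings (`q_grid`,
#' `s1_threshold`, `in_gate`).
#'
#' @param ... Overrides merged over the defaults (unknown keys are rejected).
#' @return A validated config list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = "emgknee_run",
    analysis_rate = 100,
    kpe = 5,
    subject = list(),
    ga = list(),
    sobol = list(samples = 1024, sequence = "sobol"),
    simplify = list(q_grid = c(4, 10, 16, 26), s1_threshold = 0.05,
                    in_gate = 0.1, s2_threshold = 0.05),
    log_level = "info"
  )
  validate_config(utils::modifyList(cfg, list(...)))
}

#' Validate a run configuration
#'
#' Rejects unknown top-level keys and checks basic types and ranges before
#' any computation runs.
#'
#' @param cfg A config list.
#' @return The config, invisibly validated.
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown) > 0) {
    abort_config(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    abort_config("seed must be a single integer")
  }
  if (!is.numeric(cfg$analysis_rate) || cfg$analysis_rate <= 0) {
    abort_config("analysis_rate must be positive")
  }
  if (!cfg$kpe %in% c(5, 6)) abort_config("kpe must be 5 or 6")
  cfg
}

#' Read a config file (JSON or YAML)
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return A validated config list (defaults filled in).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_schema(paste("no such file:", path))
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(default_config, cfg)
}

# stable hash of a config (for artifact stamping / cache invalidation)
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 12)
  # FNV-1a over the serialized config
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Write a fitted model to JSON
#'
#' The file carries the 26 named parameter values, fit metrics, the
#' per-generation objective trace, the GA settings and the seed, so any fit
#' is reproducible from its own artifact.
#'
#' @param fit An `emg_fit` from [ga_identify()].
#' @param path Output path.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "emg_fit"))
  obj <- list(
    lambda = as.list(unclass(fit$lambda_opt)),
    metrics = fit$metrics,
    objective_trace = fit$objective_trace,
    free = param_names()[fit$free_mask],
    seed = fit$seed,
    config = fit$config[c("population_size", "max_generations", "crossover",
                          "mutation", "crossover_prob", "mutation_prob",
                          "sbx_eta", "mutation_eta", "anneal_factor",
                          "restarts", "elitism_count", "tournament_size",
                          "stall_generations")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lam <- unlist(x$lambda)[param_names()]
  structure(list(
    lambda_opt = param_vector(lam),
    metrics = as.list(x$metrics),
    objective_trace = as.numeric(x$objective_trace),
    free_mask = param_names() %in% x$free,
    seed = x$seed,
    config = as.list(x$config)
  ), class = "emg_fit")
}

#' Write a sensitivity result to JSON
#'
#' @param sens An `emg_sobol` from [sobol_analyze()].
#' @param path Output path.
#' @export
write_sensitivity <- function(sens, path) {
  stopifnot(inherits(sens, "emg_sobol"))
  obj <- list(
    terms = sens$terms, S1 = sens$S1, ST = sens$ST, INi = sens$INi,
    IN = sens$IN, f0 = sens$f0, varY = sens$varY, P = sens$P,
    pairs = if (nrow(sens$S2) > 0) sens$S2 else NULL,
    bounds = list(lower = as.numeric(sens$bounds$lower),
                  upper = as.numeric(sens$bounds$upper))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sensitivity
#' @export
read_sensitivity <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  s2 <- if (!is.null(x$pairs) && length(x$pairs) > 0) {
    tibble::as_tibble(x$pairs)
  } else {
    tibble::tibble(i = integer(), j = integer(), S2 = numeric())
  }
  structure(list(
    terms = x$terms, S1 = as.numeric(x$S1), ST = as.numeric(x$ST),
    INi = as.numeric(x$INi), IN = x$IN, f0 = x$f0, varY = x$varY, P = x$P,
    S2 = s2,
    bounds = structure(list(
      lower = stats::setNames(as.numeric(x$bounds$lower), x$terms),
      upper = stats::setNames(as.numeric(x$bounds$upper), x$terms)),
      class = "param_bounds")
  ), class = "emg_sobol")
}
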