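# error signalling -----------------------------------------------------------
# Condition classes used across the package. CLI exit codes map onto them:
# schema errors -> 2, data errors -> 3, numeric failures -> 4.

abort_invalid <- function(msg) {
  rlang::abort(msg, class = c("emgknee_invalid_input", "emgknee_error"))
}

abort_schema <- function(msg) {
  rlang::abort(msg, class = c("emgknee_schema_error", "emgknee_error"))
}

abort_data <- function(msg) {
  rlang::abort(msg, class = c("emgknee_data_error", "emgknee_error"))
}

abort_config <- function(msg) {
  rlang::abort(msg, class = c("emgknee_config_error", "emgknee_error"))
}

abort_numeric <- function(msg) {
  rlang::abort(msg, class = c("emgknee_numeric_error", "emgknee_error"))
}

inform_log <- function(...) {
  rlang::inform(paste0(...), class = "emgknee_log")
}

# seeds -----------------------------------------------------------------------

#' Derive a per-stage seed from a global seed
#'
#' Pipeline stages (simulate, identify, sensitivity, simplify) draw their
#' randomness from seeds split off a single run seed, so any stage can be
#' re-run in isolation and reproduce its part of a run.
#'
#' @param seed Integer global seed.
#' @param stage Stage name (any string).
#' @return An integer seed in `[0, 2^31)`.
#' @export
split_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 2654435) %% 2147483647)
}

# run a thunk under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# misc ------------------------------------------------------------------------

clip01 <- function(x) pmin(pmax(x, 0), 1)

is_uniform_grid <- function(t, tol = 1e-6) {
  if (length(t) < 2) return(TRUE)
  dt <- diff(t)
  max(abs(dt - dt[1])) <= tol * max(dt[1], .Machine$double.eps)
}
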