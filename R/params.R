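#' Muscle set of the knee model
#'
#' The model is driven by four thigh muscles: the long head of biceps femoris
#' (knee flexor) and the three superficial heads of quadriceps (knee
#' extensors). Vastus intermedius is omitted: it lies under rectus femoris and
#' its surface EMG cannot be isolated.
#'
#' @format A tibble with columns `muscle` (abbreviation), `name`, and `role`
#'   (`"flexor"` or `"extensor"`).
#' @export
knee_muscles <- tibble::tibble(
  muscle = c("bf", "rf", "vl", "vm"),
  name   = c("biceps femoris (long head)", "rectus femoris",
             "vastus lateralis", "vastus medialis"),
  role   = c("flexor", "extensor", "extensor", "extensor")
)

# per-muscle parameter block layout, after the 6 shared function parameters
.muscle_fields <- c("lo", "phi", "fo", "qv", "lt")
.fn_fields <- c("A", "dW_asc", "v_asc", "dW_des", "v_dec", "eps0")

#' Names of the 26 model parameters, in canonical order
#'
#' The canonical flattening order is the 6 shared function parameters
#' (`A`, `dW_asc`, `v_asc`, `dW_des`, `v_dec`, `eps0`) followed by the 5
#' muscle-tendon parameters (`lo`, `phi`, `fo`, `qv`, `lt`) of each muscle in
#' the order BF, RF, VL, VM. All serialization, bounds, masks and sensitivity
#' indices use this order.
#'
#' @return Character vector of length 26.
#' @export
param_names <- function() {
  c(.fn_fields,
    as.vector(t(outer(knee_muscles$muscle, .muscle_fields,
                      function(m, f) paste(f, m, sep = "_")))))
}

#' Construct a model parameter vector
#'
#' @param x Numeric vector of length 26 in canonical order (see
#'   [param_names()]), named or unnamed.
#' @return A named numeric vector of class `"param_vector"`.
#' @export
param_vector <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 26L) {
    abort_invalid("a parameter vector must have exactly 26 elements")
  }
  if (any(!is.finite(x))) {
    abort_invalid("parameter values must all be finite")
  }
  names(x) <- param_names()
  structure(x, class = "param_vector")
}

#' @export
print.param_vector <- function(x, ...) {
  cat("<param_vector: 26 knee-model parameters>\n")
  print(tidy(x), n = 26)
  invisible(x)
}

#' Tidy a parameter vector into a parameter table
#'
#' @param x A `param_vector`.
#' @param ... Unused.
#' @return A tibble with columns `index`, `term`, `muscle`, `quantity`,
#'   `value`. Shared function parameters have `muscle = NA`.
#' @export
tidy.param_vector <- function(x, ...) {
  nm <- param_names()
  muscle <- c(rep(NA_character_, 6L), rep(knee_muscles$muscle, each = 5L))
  quantity <- c(.fn_fields, rep(.muscle_fields, times = 4L))
  tibble::tibble(index = seq_along(nm), term = nm, muscle = muscle,
                 quantity = quantity, value = as.numeric(x))
}

#' @rdname tidy.param_vector
#' @export
tidy.param_bounds <- function(x, ...) {
  tibble::tibble(index = 1:26, term = param_names(),
                 lower = as.numeric(x$lower), upper = as.numeric(x$upper))
}

# shared function parameters as a list
fn_params <- function(lambda) {
  as.list(unclass(lambda)[1:6])
}

# one muscle's parameter block as a list (lo, phi, fo, qv, lt, role)
muscle_params <- function(lambda, muscle) {
  muscle <- match.arg(muscle, knee_muscles$muscle)
  i <- match(muscle, knee_muscles$muscle)
  block <- unclass(lambda)[6L + (i - 1L) * 5L + 1:5]
  names(block) <- .muscle_fields
  c(as.list(block),
    list(is_flexor = knee_muscles$role[i] == "flexor", muscle = muscle))
}

#' Default generic-adult initial parameter values
#'
#' Stands in for subject-specific musculoskeletal scaling: optimal fiber
#' lengths, pennation angles, maximum isometric forces and tendon lengths of
#' the four muscles are set to generic adult magnitudes from the
#' musculoskeletal modelling literature. These are the centres from which
#' [make_bounds()] derives the search box; they are a starting point, not a
#' claim about any individual.
#'
#' @return A `param_vector`.
#' @export
default_initial_params <- function() {
  param_vector(c(
    -1.5, 0.45, 3.0, 0.45, 3.0, 0.40,         # A, dW_asc, v_asc, dW_des, v_dec, eps0
    0.110, 0.20, 900,  10, 0.33,               # BF:  lo, phi, fo, qv, lt
    0.085, 0.09, 1200, 10, 0.35,               # RF
    0.100, 0.09, 1900, 10, 0.16,               # VL
    0.090, 0.05, 1300, 10, 0.13                # VM
  ))
}

#' Identification bounds for the 26 parameters
#'
#' Function-parameter bounds are fixed constants: `A` in \[-3, 0.01\],
#' curve widths in \[0.01, 1\], curve exponents in \[2, 4\], maximum passive
#' strain in \[0.2, 0.6\], and the velocity-scaling factor `qv` in \[8, 12\].
#' Muscle-tendon bounds are relative to the supplied initial values: optimal
#' fiber length within `lo_pct` (default 50%) of its initial value, and
#' pennation angle, maximum isometric force and tendon length within
#' `other_pct` (default 20%) of theirs.
#'
#' @param initial A `param_vector` of initial (e.g. scaled-model) values.
#' @param lo_pct Relative half-width for optimal fiber length.
#' @param other_pct Relative half-width for pennation, maximum force and
#'   tendon length.
#' @return An object of class `"param_bounds"`: list with named 26-vectors
#'   `lower` and `upper`.
#' @export
make_bounds <- function(initial = default_initial_params(),
                        lo_pct = 0.5, other_pct = 0.2) {
  initial <- param_vector(initial)
  if (any(unclass(initial)[grep("^(lo|fo|lt)_", param_names())] <= 0)) {
    abort_invalid("initial fiber lengths, forces and tendon lengths must be positive")
  }
  lower <- upper <- stats::setNames(numeric(26), param_names())
  fixed <- list(A = c(-3, 0.01), dW_asc = c(0.01, 1), v_asc = c(2, 4),
                dW_des = c(0.01, 1), v_dec = c(2, 4), eps0 = c(0.2, 0.6))
  for (nm in names(fixed)) {
    lower[nm] <- fixed[[nm]][1]; upper[nm] <- fixed[[nm]][2]
  }
  for (m in knee_muscles$muscle) {
    p <- muscle_params(initial, m)
    rel <- function(v, pct) c(v * (1 - pct), v * (1 + pct))
    for (f in c("lo", "phi", "fo", "lt")) {
      pct <- if (f == "lo") lo_pct else other_pct
      b <- rel(p[[f]], pct)
      lower[paste(f, m, sep = "_")] <- min(b); upper[paste(f, m, sep = "_")] <- max(b)
    }
    lower[paste("qv", m, sep = "_")] <- 8; upper[paste("qv", m, sep = "_")] <- 12
  }
  if (any(lower >= upper)) {
    abort_invalid("degenerate bounds: every lower bound must be below its upper bound")
  }
  structure(list(lower = lower, upper = upper), class = "param_bounds")
}

#' @export
print.param_bounds <- function(x, ...) {
  cat("<param_bounds: box constraints on the 26 knee-model parameters>\n")
  print(tidy(x), n = 26)
  invisible(x)
}

#' Serialize / deserialize parameter vectors as JSON
#'
#' Parameters are written as a named object in the canonical 26-element
#' order, so files are self-describing and order-stable.
#'
#' @param lambda A `param_vector`.
#' @param path File path.
#' @return `read_params()` returns a `param_vector`; `write_params()` returns
#'   `path` invisibly.
#' @export
write_params <- function(lambda, path) {
  lambda <- param_vector(lambda)
  jsonlite::write_json(as.list(unclass(lambda)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- unlist(x)
  if (!all(param_names() %in% names(x))) {
    abort_schema(paste("parameter file is missing:",
                       paste(setdiff(param_names(), names(x)), collapse = ", ")))
  }
  param_vector(x[param_names()])
}
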