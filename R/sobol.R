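#' Variance-based (Sobol') sensitivity analysis
#'
#' The model output studied is the disturbance functional: with the dataset's
#' signal sequences held fixed and `lambda0` the identified optimum,
#' `Y(lambda) = (1/N) * sum((tau_n(lambda) - tau_n(lambda0))^2)`, i.e. the
#' mean squared torque disturbance caused by replacing the optimal parameters
#' with arbitrary ones. First-order indices `S1` measure each parameter's
#' main effect on `Y`; total indices `ST` add all its interactions;
#' second-order indices `S2` isolate pairwise interactions. The global
#' interaction index is `IN = 1 - sum(S1)` and the per-parameter interaction
#' index `INi = ST - S1`.
#'
#' @name sobol_sensitivity
NULL

#' Disturbance output functional
#'
#' Returns a vectorized function mapping a chromosome matrix (rows =
#' parameter vectors) to the scalar disturbance output `Y` against the
#' reference torque produced by `lambda0` on `data`. `Y(lambda0) = 0` and
#' `Y >= 0` by construction.
#'
#' @param data Aligned dataset (reference torque is not used; the comparison
#'   torque is regenerated from `lambda0`).
#' @param lambda0 The identified optimal [param_vector()].
#' @param kpe Passive shape constant.
#' @return `function(L)` taking an `m x 26` matrix (or a 26-vector) and
#'   returning `m` outputs.
#' @export
output_functional <- function(data, lambda0, kpe = 5) {
  prep <- if (inherits(data, "emgknee_prep")) data else prepare_dataset(data)
  lambda0 <- param_vector(lambda0)
  tau0 <- as.numeric(forward_torque_matrix(prep,
                                           matrix(unclass(lambda0), 1), kpe))
  function(L) {
    if (is.null(dim(L))) L <- matrix(L, nrow = 1)
    tau <- forward_torque_matrix(prep, L, kpe)
    ref <- matrix(tau0, nrow(tau), ncol(tau), byrow = TRUE)
    rowMeans((tau - ref)^2)
  }
}

#' Saltelli-style sample design
#'
#' Two independent `P x d` sample matrices `A` and `B` in the bounded
#' parameter box, drawn from a scrambled Sobol' sequence (one `2d`-dimensional
#' stream split into two blocks), a Latin hypercube, or plain uniform
#' sampling. Pick matrices `AB(i)` (A with column i from B) and `BA(ij)`
#' (B with columns i and j from A) are produced on demand by
#' [design_pick()].
#'
#' @param bounds A [make_bounds()] object, or a list with numeric `lower`
#'   and `upper` vectors of equal length (defining `d`).
#' @param P Samples per matrix; for the Sobol' sequence a power of two is
#'   expected (anything else is rounded up with a warning).
#' @param seed RNG seed controlling the scramble / draws.
#' @param sequence `"sobol"`, `"latin"` or `"uniform"`.
#' @return An object of class `sobol_design` with matrices `A`, `B` (rows
#'   within bounds), `P`, `d`, `sequence`, `seed`.
#' @export
sobol_design <- function(bounds, P = 1024, seed = NULL,
                         sequence = c("sobol", "latin", "uniform")) {
  sequence <- match.arg(sequence)
  lower <- as.numeric(bounds$lower); upper <- as.numeric(bounds$upper)
  d <- length(lower)
  if (sequence == "sobol" && bitwAnd(P, P - 1L) != 0L) {
    P2 <- 2^ceiling(log2(P))
    rlang::warn(sprintf(
      "P = %d is not a power of two; rounded up to %d for the Sobol' sequence",
      P, P2))
    P <- P2
  }
  U <- with_seed(seed, switch(
    sequence,
    sobol = sobol_points(P, 2 * d, scramble = TRUE),
    latin = {
      # two independent Latin hypercubes
      one <- function() vapply(seq_len(d), function(j)
        (sample.int(P) - stats::runif(P)) / P, numeric(P))
      cbind(one(), one())
    },
    uniform = matrix(stats::runif(P * 2 * d), P, 2 * d)
  ))
  scale <- function(M) sweep(sweep(M, 2, upper - lower, "*"), 2, lower, "+")
  structure(list(A = scale(U[, 1:d, drop = FALSE]),
                 B = scale(U[, d + 1:d, drop = FALSE]),
                 P = P, d = d, sequence = sequence, seed = seed,
                 bounds = list(lower = lower, upper = upper)),
            class = "sobol_design")
}

#' Pick matrices of a Saltelli design
#'
#' `design_pick(design, i)` returns `AB(i)`: matrix `A` with column `i`
#' replaced by column `i` of `B`. `design_pick(design, i, from = "B")`
#' returns `BA(i)`. `design_pick_pair(design, i, j)` returns `BA(ij)`: `B`
#' with columns `i` and `j` taken from `A`.
#'
#' @param design A [sobol_design()].
#' @param i,j Column indices.
#' @param from Base matrix: `"A"` gives `AB(i)`, `"B"` gives `BA(i)`.
#' @return A `P x d` matrix.
#' @export
design_pick <- function(design, i, from = c("A", "B")) {
  from <- match.arg(from)
  if (from == "A") {
    M <- design$A; M[, i] <- design$B[, i]
  } else {
    M <- design$B; M[, i] <- design$A[, i]
  }
  M
}

#' @rdname design_pick
#' @export
design_pick_pair <- function(design, i, j) {
  if (i == j) abort_invalid("second-order pairs need two distinct indices")
  M <- design$B
  M[, c(i, j)] <- design$A[, c(i, j)]
  M
}

# estimators ------------------------------------------------------------------

# mean and (biased, 1/P) variance of the output, from f(A)
output_moments <- function(fA) {
  f0 <- mean(fA)
  varY <- mean(fA^2) - f0^2
  list(f0 = f0, varY = varY)
}

check_var <- function(varY) {
  if (!is.finite(varY) || varY <= 0) {
    abort_numeric("output variance is zero; sensitivity indices are undefined")
  }
}

#' First-order Sobol' index estimator
#'
#' `S1_i = mean(f(B) * (f(AB_i) - f(A))) / Var(Y)`, with the output mean and
#' variance estimated from `f(A)`.
#'
#' @param fA,fB Output vectors on the `A` and `B` matrices (length `P`).
#' @param fAB Output matrix on the `AB(i)` matrices (`P x d`), or a vector
#'   for a single parameter.
#' @return Numeric vector of first-order indices.
#' @export
first_order_indices <- function(fA, fB, fAB) {
  if (is.null(dim(fAB))) fAB <- matrix(fAB, ncol = 1)
  mom <- output_moments(fA)
  check_var(mom$varY)
  colMeans(fB * (fAB - fA)) / mom$varY
}

#' Total-effect Sobol' index estimator
#'
#' `ST_i = mean(f(A) * (f(A) - f(AB_i))) / Var(Y)`: the numerator estimates
#' the total-effect variance `Var(Y) - Var_{~i}(E(Y | lambda_{~i}))`.
#'
#' @inheritParams first_order_indices
#' @return Numeric vector of total-effect indices.
#' @export
total_indices <- function(fA, fAB) {
  if (is.null(dim(fAB))) fAB <- matrix(fAB, ncol = 1)
  mom <- output_moments(fA)
  check_var(mom$varY)
  colMeans(fA * (fA - fAB)) / mom$varY
}

#' Second-order Sobol' index estimator
#'
#' `S2_ij = (mean(f(A) * f(BA_ij)) - f0^2) / Var(Y) - S1_i - S1_j`: the
#' closed second-order effect of the pair after removing both main effects.
#'
#' @param fA Output vector on `A`.
#' @param fBA_ij Output vector on `BA(ij)`.
#' @param S1_i,S1_j First-order indices of the two parameters.
#' @param f0,varY Output mean and variance (from [output_moments()] on
#'   `f(A)`).
#' @return The second-order index (scalar).
#' @export
second_order_index <- function(fA, fBA_ij, S1_i, S1_j, f0, varY) {
  check_var(varY)
  (mean(fA * fBA_ij) - f0^2) / varY - S1_i - S1_j
}

#' Screen parameter pairs for second-order analysis
#'
#' Second-order indices are expensive (one model batch per pair), so pairs
#' are only evaluated when interactions are globally material
#' (`IN > in_gate`) and then only among parameters whose interaction index
#' `INi = ST - S1` exceeds `threshold`.
#'
#' @param result An `emg_sobol` (or any list with `S1`, `ST`, `IN`).
#' @param threshold Per-parameter interaction threshold (default 0.05).
#' @param in_gate Global interaction gate (default 0.1).
#' @return Tibble of pairs with columns `i`, `j` (i < j); zero rows when
#'   nothing needs checking.
#' @export
interaction_screen <- function(result, threshold = 0.05, in_gate = 0.1) {
  INi <- result$ST - result$S1
  IN <- 1 - sum(result$S1)
  idx <- which(INi > threshold)
  if (IN <= in_gate || length(idx) < 2) {
    return(tibble::tibble(i = integer(0), j = integer(0)))
  }
  cmb <- utils::combn(sort(idx), 2)
  tibble::tibble(i = cmb[1, ], j = cmb[2, ])
}

#' Run a full Sobol' sensitivity analysis
#'
#' Evaluates the model on `A`, `B` and the `d` pick matrices `AB(i)`
#' (`d + 2` batches of `P` runs), forms `S1`, `ST`, `INi`, `IN`, then
#' evaluates `BA(ij)` only for screened pairs to obtain `S2`.
#'
#' @param f Vectorized model: `function(L)` mapping a `P x d` matrix to `P`
#'   outputs (e.g. from [output_functional()]).
#' @param design A [sobol_design()].
#' @param threshold,in_gate Screening thresholds (see
#'   [interaction_screen()]).
#' @param second_order `"auto"` (screened), `"none"`, or `"all"` pairs.
#' @param terms Optional parameter names (defaults to [param_names()] when
#'   `d == 26`).
#' @return An object of class `emg_sobol` with elements `terms`, `S1`, `ST`,
#'   `INi`, `IN`, `S2` (tibble `i`, `j`, `S2`), `f0`, `varY`, `P`, `bounds`.
#' @export
sobol_analyze <- function(f, design, threshold = 0.05, in_gate = 0.1,
                          second_order = c("auto", "none", "all"),
                          terms = NULL) {
  second_order <- match.arg(second_order)
  d <- design$d
  if (is.null(terms)) {
    terms <- if (d == 26) param_names() else paste0("x", seq_len(d))
  }
  fA <- f(design$A)
  fB <- f(design$B)
  fAB <- vapply(seq_len(d), function(i) f(design_pick(design, i)),
                numeric(design$P))
  mom <- output_moments(fA)
  check_var(mom$varY)
  S1 <- first_order_indices(fA, fB, fAB)
  ST <- total_indices(fA, fAB)
  res <- list(terms = terms, S1 = S1, ST = ST, INi = ST - S1,
              IN = 1 - sum(S1), f0 = mom$f0, varY = mom$varY, P = design$P,
              bounds = structure(list(
                lower = stats::setNames(design$bounds$lower, terms),
                upper = stats::setNames(design$bounds$upper, terms)),
                class = "param_bounds"))
  pairs <- switch(second_order,
    none = tibble::tibble(i = integer(0), j = integer(0)),
    auto = interaction_screen(res, threshold, in_gate),
    all = {
      cmb <- utils::combn(d, 2)
      tibble::tibble(i = cmb[1, ], j = cmb[2, ])
    })
  S2 <- purrr::map2_dbl(pairs$i, pairs$j, function(i, j) {
    second_order_index(fA, f(design_pick_pair(design, i, j)),
                       S1[i], S1[j], mom$f0, mom$varY)
  })
  res$S2 <- tibble::tibble(i = pairs$i, j = pairs$j, S2 = S2)
  structure(res, class = "emg_sobol")
}

#' @export
print.emg_sobol <- function(x, ...) {
  cat(sprintf("<emg_sobol: %d parameters, P = %d>\n", length(x$S1), x$P))
  cat(sprintf("  Var(Y) = %.4g, IN = %.4g\n", x$varY, x$IN))
  top <- order(x$ST, decreasing = TRUE)[seq_len(min(6, length(x$ST)))]
  for (i in top) {
    cat(sprintf("  %-8s S1 = %7.4f  ST = %7.4f\n", x$terms[i], x$S1[i],
                x$ST[i]))
  }
  if (nrow(x$S2) > 0) {
    cat(sprintf("  %d second-order pair(s) evaluated\n", nrow(x$S2)))
  }
  invisible(x)
}

#' Tidiers for sensitivity results
#'
#' `tidy()` gives one row per parameter (`S1`, `ST`, `INi`); `glance()` a
#' one-row summary (`f0`, `varY`, `IN`, `P`, pairs evaluated).
#'
#' @param x An `emg_sobol`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.emg_sobol <- function(x, ...) {
  tibble::tibble(index = seq_along(x$S1), term = x$terms, S1 = x$S1,
                 ST = x$ST, INi = x$INi)
}

#' @rdname tidy.emg_sobol
#' @export
glance.emg_sobol <- function(x, ...) {
  tibble::tibble(f0 = x$f0, varY = x$varY, IN = x$IN, P = x$P,
                 n_pairs = nrow(x$S2))
}
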