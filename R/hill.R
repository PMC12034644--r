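#' Hill-type muscle model primitives
#'
#' The contractile machinery of each muscle is described by a Hill-type model:
#' a contractile element (CE) whose force is the product of a maximum
#' isometric force, an active force-length gain, a force-velocity gain and the
#' neural activation, in parallel with a passive elastic element (PE), both
#' acting through a fixed-length tendon at a pennation angle to the line of
#' action. These functions implement the individual curves; they are
#' vectorized over samples.
#'
#' @name hill_curves
NULL

#' Pennation angle at a given fiber length
#'
#' Fiber "height" lo*sin(phi_o) is conserved as the fiber shortens or
#' lengthens, so the instantaneous pennation angle is
#' `asin(lo * sin(phi_o) / l_m)`, with the argument clamped to \[0, 1\].
#'
#' @param l_m Fiber length, m (positive).
#' @param lo Optimal fiber length, m.
#' @param phi_o Optimal pennation angle, rad.
#' @return Pennation angle in rad, in \[0, pi/2\].
#' @export
pennation_angle <- function(l_m, lo, phi_o) {
  if (any(l_m <= 0)) abort_invalid("fiber length must be positive")
  asin(clip01(lo * sin(phi_o) / l_m))
}

#' Fiber length from muscle-tendon length
#'
#' With a fixed tendon length and conserved fiber height, the fiber length is
#' the hypotenuse `sqrt((l_mt - lt)^2 + (lo*sin(phi_o))^2)`. When an extreme
#' parameter combination makes `l_mt <= lt`, the along-tendon component is
#' floored at zero (and the fiber length at `1e-6 * lo` for parallel-fibered
#' muscles) so that downstream objectives stay finite; a warning reports how
#' many samples were floored.
#'
#' @param l_mt Muscle-tendon length, m.
#' @param lo Optimal fiber length, m.
#' @param phi_o Optimal pennation angle, rad.
#' @param lt Tendon length, m.
#' @return Fiber length, m (always `>= lo*sin(phi_o)` up to the floor rule).
#' @export
fiber_length <- function(l_mt, lo, phi_o, lt) {
  h <- lo * sin(phi_o)
  dx <- l_mt - lt
  n_bad <- sum(dx <= 0)
  if (n_bad > 0) {
    rlang::warn(sprintf(
      "degenerate geometry: l_mt <= lt at %d sample(s); fiber length floored",
      n_bad), class = "emgknee_degenerate_geometry")
  }
  pmax(sqrt(pmax(dx, 0)^2 + h^2), 1e-6 * lo)
}

#' EMG-to-activation nonlinearity
#'
#' Maps normalized EMG `u` in \[0, 1\] to activation via
#' `a = (exp(A*u) - 1) / (exp(A) - 1)`. The shape parameter `A` ranges from
#' strongly nonlinear (-3) to essentially linear (0.01); as `A -> 0` the map
#' tends to the identity, which is returned analytically for `|A| < 1e-6`.
#' Inputs outside \[0, 1\] are clipped with a warning.
#'
#' @param u Normalized EMG, in \[0, 1\].
#' @param A Nonlinearity shape parameter, in \[-3, 0.01\].
#' @return Activation in \[0, 1\]; `a(0) = 0`, `a(1) = 1`.
#' @export
activation <- function(u, A) {
  n_clip <- sum(u < 0 | u > 1)
  if (n_clip > 0) {
    rlang::warn(sprintf("normalized EMG outside [0, 1] at %d sample(s); clipped",
                        n_clip), class = "emgknee_clipped_input")
    u <- clip01(u)
  }
  if (abs(A) < 1e-6) return(u)
  expm1(A * u) / expm1(A)
}

# inverse of the activation map (used by the synthetic generator)
activation_inverse <- function(a, A) {
  a <- clip01(a)
  if (abs(A) < 1e-6) return(a)
  log1p(a * expm1(A)) / A
}

#' Active force-length curve
#'
#' Two half bell curves joined at the optimum: for normalized fiber length
#' `l_bar <= 1` the gain is `exp(-(|l_bar-1|/dW_asc)^v_asc)`, and above 1 it
#' is `exp(-((l_bar-1)/dW_des)^v_dec)`. The absolute value keeps non-integer
#' exponents well defined on the ascending side. The maximum, exactly 1, is
#' attained at `l_bar = 1`.
#'
#' @param l_bar Normalized fiber length `l_m / lo` (positive).
#' @param dW_asc,v_asc Width and exponent of the ascending limb.
#' @param dW_des,v_dec Width and exponent of the descending limb.
#' @return Dimensionless gain in (0, 1\].
#' @export
force_length <- function(l_bar, dW_asc, v_asc, dW_des, v_dec) {
  d <- abs(l_bar - 1)
  ifelse(l_bar <= 1,
         exp(-(d / dW_asc)^v_asc),
         exp(-(d / dW_des)^v_dec))
}

#' Force-velocity curve
#'
#' Hill hyperbola on the concentric (shortening, `v_bar <= 0`) side,
#' `0.3*(v_bar + 1)/(0.3 - v_bar)`, clamped to 0 below the maximum shortening
#' velocity `v_bar = -1`; on the eccentric side
#' `(2.34*v_bar + 0.039)/(1.3*v_bar + 0.039)`, capped at its asymptote 1.8.
#' Both branches equal 1 at `v_bar = 0`. The normalized velocity is
#' `v_m / (qv * lo)` with shortening negative.
#'
#' @param v_bar Normalized fiber velocity.
#' @return Dimensionless gain in \[0, 1.8\].
#' @export
force_velocity <- function(v_bar) {
  conc <- 0.3 * (v_bar + 1) / (0.3 - v_bar)
  ecc <- (2.34 * v_bar + 0.039) / (1.3 * v_bar + 0.039)
  out <- ifelse(v_bar <= 0, pmax(conc, 0), pmin(ecc, 1.8))
  out
}

#' Passive force-length curve
#'
#' The parallel elastic element is slack at and below the optimal fiber
#' length and loads exponentially above it:
#' `(exp(kpe*(l_bar-1)/eps0) - 1) / (exp(kpe) - 1)`, reaching 1 exactly at
#' strain `eps0`. The shape constant `kpe` is fixed by age group (5 for young
#' adults, 6 for older) and is not identified. Beyond the maximum strain the
#' curve is continued linearly (tangent at `l_bar = 1 + eps0`): the
#' exponential toe region is only calibrated up to `eps0`, and extrapolating
#' it over the full identification box produces astronomic forces that
#' destroy objective and variance estimates, so the tail is kept
#' C1-continuous but polynomial.
#'
#' @param l_bar Normalized fiber length.
#' @param eps0 Maximum passive strain, in \[0.2, 0.6\].
#' @param kpe Passive shape constant, 5 or 6.
#' @return Dimensionless gain, 0 on `l_bar <= 1`, monotone above, exactly 1
#'   at `l_bar = 1 + eps0`.
#' @export
passive_force <- function(l_bar, eps0, kpe = 5) {
  strain <- pmax(l_bar - 1, 0)
  slope <- kpe * exp(kpe) / (eps0 * expm1(kpe))   # tangent at maximum strain
  ifelse(strain <= eps0,
         expm1(kpe * strain / eps0) / expm1(kpe),
         1 + slope * (strain - eps0))
}

#' Muscle-tendon force of one muscle
#'
#' Composes the Hill-type components:
#' `F = (Fo * fL(l_bar) * fV(v_bar) * a(u) + Fo * fPE(l_bar)) * cos(phi)`
#' with `l_bar = l_m/lo`, `v_bar = v_m/(qv*lo)` and `phi` the instantaneous
#' pennation angle. Both active and passive terms act along the fiber and are
#' projected onto the tendon by `cos(phi)`.
#'
#' @param l_m Fiber length, m.
#' @param v_m Fiber velocity, m/s (shortening negative).
#' @param u Normalized EMG in \[0, 1\].
#' @param p Muscle parameter list with `lo`, `phi`, `fo`, `qv` (as produced
#'   internally from a [param_vector()]), or a named list/vector with those
#'   fields.
#' @param fn Function-parameter list with `A`, `dW_asc`, `v_asc`, `dW_des`,
#'   `v_dec`, `eps0`.
#' @param kpe Passive shape constant.
#' @return Force along the tendon, N (nonnegative).
#' @export
muscle_tendon_force <- function(l_m, v_m, u, p, fn, kpe = 5) {
  p <- as.list(p); fn <- as.list(fn)
  l_bar <- l_m / p$lo
  v_bar <- v_m / (p$qv * p$lo)
  phi <- pennation_angle(l_m, p$lo, p$phi)
  a <- activation(u, fn$A)
  fl <- force_length(l_bar, fn$dW_asc, fn$v_asc, fn$dW_des, fn$v_dec)
  fv <- force_velocity(v_bar)
  fpe <- passive_force(l_bar, fn$eps0, kpe)
  p$fo * (fl * fv * a + fpe) * cos(phi)
}

#' Net knee torque from the four muscle states
#'
#' Sums the flexor muscle torque and subtracts the extensor torques
#' (flexion positive): `tau = sum(F*r, flexors) - sum(F*r, extensors)`.
#' Moment arms are magnitudes; the sign is carried by the muscle role.
#'
#' @param states A data frame with one row per muscle in the order BF, RF,
#'   VL, VM and columns `l_mt` (m), `v_mt` (m/s, d l_mt/dt), `u`
#'   (normalized EMG) and `r` (moment arm magnitude, m).
#' @param lambda A [param_vector()].
#' @param kpe Passive shape constant.
#' @return Knee torque, N m.
#' @export
knee_torque <- function(states, lambda, kpe = 5) {
  states <- as.data.frame(states)
  if (nrow(states) != 4L) abort_invalid("knee_torque needs exactly 4 muscle states")
  lambda <- param_vector(lambda)
  fn <- fn_params(lambda)
  tau <- 0
  for (i in seq_len(4L)) {
    p <- muscle_params(lambda, knee_muscles$muscle[i])
    l_m <- fiber_length(states$l_mt[i], p$lo, p$phi, p$lt)
    # chain rule: d l_m/dt = (l_mt - lt)/l_m * d l_mt/dt
    v_m <- pmax(states$l_mt[i] - p$lt, 0) / l_m * states$v_mt[i]
    f <- muscle_tendon_force(l_m, v_m, states$u[i], p, fn, kpe)
    tau <- tau + (if (p$is_flexor) 1 else -1) * f * states$r[i]
  }
  tau
}

# dataset preparation ---------------------------------------------------------

# Columns an aligned analysis dataset must carry (tau_ref optional for pure
# forward simulation).
dataset_columns <- function(with_torque = TRUE) {
  cols <- c("time_s",
            paste0("u_", knee_muscles$muscle),
            paste0("lmt_", knee_muscles$muscle),
            paste0("r_", knee_muscles$muscle))
  if (with_torque) cols <- c(cols, "tau_ref")
  cols
}

# Precompute everything about a dataset that does not depend on lambda:
# per-muscle l_mt, u, r and the muscle-tendon velocity d l_mt/dt (smoothed
# central differences). Returned object is consumed by the batch engine.
prepare_dataset <- function(data, smooth_velocity = TRUE) {
  data <- tibble::as_tibble(data)
  need <- dataset_columns(with_torque = FALSE)
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort_schema(paste("dataset is missing column(s):",
                       paste(missing, collapse = ", ")))
  }
  t <- data$time_s
  if (length(t) < 2 || any(diff(t) <= 0)) {
    abort_data("dataset time base must be strictly increasing with >= 2 samples")
  }
  if (!is_uniform_grid(t)) {
    abort_data("dataset time base must be uniform; resample with synchronize()")
  }
  rate <- 1 / mean(diff(t))
  muscles <- knee_muscles$muscle
  prep <- list(
    time = t, n = length(t), rate = rate,
    tau_ref = if ("tau_ref" %in% names(data)) data$tau_ref else NULL,
    u = lapply(muscles, function(m) clip01(data[[paste0("u_", m)]])),
    lmt = lapply(muscles, function(m) data[[paste0("lmt_", m)]]),
    r = lapply(muscles, function(m) abs(data[[paste0("r_", m)]])),
    sign = ifelse(knee_muscles$role == "flexor", 1, -1)
  )
  prep$vmt <- lapply(prep$lmt, function(l) {
    deriv_series(l, rate, smooth = smooth_velocity && length(l) > 30)
  })
  names(prep$u) <- names(prep$lmt) <- names(prep$r) <- names(prep$vmt) <- muscles
  if (any(vapply(c(prep$u, prep$lmt, prep$r), function(x) any(!is.finite(x)),
                 logical(1)))) {
    abort_data("dataset contains non-finite values")
  }
  prep$lmt_mat <- do.call(cbind, prep$lmt)
  prep$vmt_mat <- do.call(cbind, prep$vmt)
  prep$u_mat <- do.call(cbind, prep$u)
  prep$r_mat <- do.call(cbind, prep$r)
  structure(prep, class = "emgknee_prep")
}

# batch forward engine --------------------------------------------------------

# Evaluate the forward model for a population of chromosomes at once.
# L: pop x 26 matrix (canonical order). Returns a pop x n torque matrix
# (rows are chromosomes, columns are time samples). The compiled kernel
# carries the whole GA / sensitivity workload; the vectorized R twin below
# is kept as an independent reference implementation for testing.
forward_torque_matrix <- function(prep, L, kpe = 5) {
  if (is.null(dim(L))) L <- matrix(L, nrow = 1)
  forward_torque_core(L, prep$lmt_mat, prep$vmt_mat, prep$u_mat, prep$r_mat,
                      prep$sign, kpe)
}

forward_torque_matrix_r <- function(prep, L, kpe = 5) {
  if (is.null(dim(L))) L <- matrix(L, nrow = 1)
  pop <- nrow(L); n <- prep$n
  tau <- matrix(0, pop, n)
  # A = 0 is the identity limit; nudge to keep expm1 ratios finite (error
  # O(A) ~ 1e-9, far below the 1e-6 analytic-limit threshold of activation())
  A <- L[, 1]; A[abs(A) < 1e-9] <- 1e-9
  eA <- expm1(A)
  dWa <- L[, 2]; va <- L[, 3]; dWd <- L[, 4]; vd <- L[, 5]; e0 <- L[, 6]
  ekpe <- expm1(kpe)
  rep_row <- function(v) matrix(v, pop, n, byrow = TRUE)   # sample-wise
  for (i in seq_len(4L)) {
    off <- 6L + (i - 1L) * 5L
    lo <- L[, off + 1L]; phi <- L[, off + 2L]; fo <- L[, off + 3L]
    qv <- L[, off + 4L]; lt <- L[, off + 5L]
    h2 <- (lo * sin(phi))^2
    DX <- rep_row(prep$lmt[[i]]) - lt
    DX[DX < 0] <- 0
    LM <- pmax(sqrt(DX * DX + h2), 1e-6 * lo)
    cphi <- DX / LM
    lbar <- LM / lo
    vbar <- cphi * rep_row(prep$vmt[[i]]) / (qv * lo)
    # activation (shape parameter recycles per chromosome row)
    a <- expm1(A * rep_row(prep$u[[i]])) / eA
    # force-length: select width/exponent per branch arithmetically
    d <- abs(lbar - 1)
    asc <- (lbar <= 1) + 0
    W <- dWd + (dWa - dWd) * asc
    V <- vd + (va - vd) * asc
    fl <- exp(-(d / W)^V)
    # force-velocity: evaluate each branch on its clamped domain
    vn <- pmin(vbar, 0); vp <- pmax(vbar, 0)
    conc <- pmax(0.3 * (vn + 1) / (0.3 - vn), 0)
    ecc <- pmin((2.34 * vp + 0.039) / (1.3 * vp + 0.039), 1.8)
    fv <- conc + (ecc - 1) * (vbar > 0)
    # passive: expm1 of the clamped strain vanishes below the optimum;
    # linear continuation beyond the maximum strain e0
    strain <- pmax(lbar - 1, 0)
    over <- pmax(strain - e0, 0)
    fpe <- expm1((strain - over) * (kpe / e0)) / ekpe +
      over * (kpe * exp(kpe) / (e0 * ekpe))
    Fmt <- fo * (fl * fv * a + fpe) * cphi
    tau <- tau + (prep$sign[i] * Fmt) * rep_row(prep$r[[i]])
  }
  tau
}

#' Forward-simulate the knee torque time series
#'
#' Runs the four-muscle model over an aligned dataset: fiber kinematics are
#' derived from the muscle-tendon length series (velocity by smoothed central
#' differences and the chain rule), activations from the normalized EMG
#' channels, and the per-muscle forces are combined into net knee torque with
#' flexion positive.
#'
#' @param data Aligned analysis dataset: a data frame with columns `time_s`,
#'   `u_<muscle>`, `lmt_<muscle>`, `r_<muscle>` for the four muscles
#'   bf/rf/vl/vm.
#' @param lambda A [param_vector()].
#' @param kpe Passive shape constant (5 young adults, 6 older).
#' @return A tibble with columns `time_s` and `tau` (N m).
#' @export
forward_torque <- function(data, lambda, kpe = 5) {
  prep <- if (inherits(data, "emgknee_prep")) data else prepare_dataset(data)
  lambda <- param_vector(lambda)
  tau <- forward_torque_matrix(prep, matrix(unclass(lambda), nrow = 1), kpe)
  tibble::tibble(time_s = prep$time, tau = as.numeric(tau))
}
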