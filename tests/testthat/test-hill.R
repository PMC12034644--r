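test_that("pennation angle follows the conserved-height geometry", {
  expect_equal(pennation_angle(0.10, lo = 0.10, phi_o = 0.2), 0.2)
  expect_equal(pennation_angle(0.37, lo = 0.10, phi_o = 0), 0)
  # closed form at an off-optimal fiber length
  expect_equal(pennation_angle(0.12, lo = 0.10, phi_o = 0.20),
               asin(0.10 * sin(0.20) / 0.12))
  # clamped when the fiber is shorter than its height
  expect_equal(pennation_angle(0.01, lo = 0.10, phi_o = 0.5), pi / 2)
  expect_error(pennation_angle(-0.1, 0.1, 0.2), class = "emgknee_invalid_input")
})

test_that("fiber length is the hypotenuse over the tendon-aligned span", {
  expect_equal(fiber_length(0.34, lo = 0.10, phi_o = 0, lt = 0.25), 0.09)
  expect_equal(suppressWarnings(fiber_length(0.25, lo = 0.10, phi_o = 0.3,
                                             lt = 0.25)),
               0.10 * sin(0.3))
  expect_equal(fiber_length(0.34, lo = 0.10, phi_o = 0.3, lt = 0.25),
               sqrt(0.09^2 + (0.10 * sin(0.3))^2))
  # degenerate geometry floors with a warning instead of going complex
  expect_warning(out <- fiber_length(0.20, 0.10, 0, 0.25),
                 class = "emgknee_degenerate_geometry")
  expect_equal(out, 1e-6 * 0.10)
})

test_that("activation nonlinearity is anchored at 0 and 1 and monotone", {
  for (A in c(-3, -1, 0.01)) {
    expect_equal(activation(0, A), 0)
    expect_equal(activation(1, A), 1)
    u <- seq(0, 1, 0.01)
    expect_true(all(diff(activation(u, A)) > 0))
  }
  expect_equal(activation(0.5, -3), (exp(-1.5) - 1) / (exp(-3) - 1))
  # A -> 0 limit converges uniformly to the identity
  u <- seq(0, 1, 0.001)
  expect_lt(max(abs(activation(u, -1e-6) - u)), 1e-4)
  expect_warning(activation(1.2, -1), class = "emgknee_clipped_input")
})

test_that("force-length curve peaks at 1 at the optimal length", {
  expect_equal(force_length(1, 0.3, 3, 0.4, 2.5), 1)
  expect_equal(force_length(1 - 0.3, 0.3, 3, 0.4, 2.5), exp(-1))
  expect_equal(force_length(1 + 0.4, 0.3, 3, 0.4, 2.5), exp(-1))
  # symmetric widths/exponents give a symmetric bell
  x <- seq(0.05, 0.45, 0.05)
  expect_equal(force_length(1 - x, 0.3, 2.6, 0.3, 2.6),
               force_length(1 + x, 0.3, 2.6, 0.3, 2.6))
  # non-integer exponents stay real on the ascending limb
  expect_true(all(is.finite(force_length(seq(0.3, 1.7, 0.1), 0.35, 2.7,
                                         0.45, 3.3))))
})

test_that("force-velocity branches join at 1 and respect their limits", {
  expect_equal(force_velocity(0), 1)
  expect_equal(force_velocity(-1), 0)
  expect_equal(force_velocity(-2), 0)      # clamped beyond max shortening
  expect_equal(force_velocity(1e9), 1.8, tolerance = 1e-6)
  expect_equal(force_velocity(1e-12), 1, tolerance = 1e-9)
  v <- seq(-1, 1, 0.01)
  expect_true(all(diff(force_velocity(v)) >= 0))
})

test_that("passive force is slack below optimum and 1 at maximum strain", {
  expect_equal(passive_force(0.9, eps0 = 0.3), 0)
  expect_equal(passive_force(1, eps0 = 0.3), 0)
  expect_equal(passive_force(1.3, eps0 = 0.3), 1)
  expect_equal(passive_force(1.15, eps0 = 0.3, kpe = 5),
               (exp(2.5) - 1) / (exp(5) - 1))
  l <- seq(0.8, 1.6, 0.01)
  expect_true(all(diff(passive_force(l, 0.4)) >= 0))
})

test_that("muscle-tendon force composes the component curves", {
  p <- list(lo = 0.10, phi = 0.2, fo = 1000, qv = 10, lt = 0.25)
  fn <- list(A = -2, dW_asc = 0.35, v_asc = 3, dW_des = 0.4, v_dec = 2.5,
             eps0 = 0.3)
  # all gains at unity -> maximum isometric force
  expect_equal(muscle_tendon_force(0.10, 0, 1, within(p, phi <- 0), fn), 1000)
  # zero activation at optimal length -> zero force
  expect_equal(muscle_tendon_force(0.10, 0, 0, p, fn), 0)
  # composition equals the product of the factor oracles
  l_m <- 0.11; v_m <- -0.2; u <- 0.5
  expected <- 1000 * (force_length(1.1, fn$dW_asc, fn$v_asc, fn$dW_des,
                                   fn$v_dec) *
                        force_velocity(v_m / (10 * 0.10)) *
                        activation(0.5, -2) +
                      passive_force(1.1, 0.3)) *
    cos(pennation_angle(0.11, 0.10, 0.2))
  expect_equal(muscle_tendon_force(l_m, v_m, u, p, fn), expected)
  # nonnegative over a sweep of admissible states
  grid <- expand.grid(l = seq(0.06, 0.16, 0.02), v = seq(-0.3, 0.3, 0.1),
                      u = c(0, 0.5, 1))
  ff <- muscle_tendon_force(grid$l, grid$v, grid$u, p, fn)
  expect_true(all(ff >= 0))
})

test_that("knee torque is a signed sum over muscle roles", {
  lambda <- default_initial_params()
  # place every fiber slightly below its optimal length so the passive
  # element is slack and force is purely activation-driven
  mk_states <- function(u) {
    l_mt <- sapply(knee_muscles$muscle, function(m) {
      p <- emgknee:::muscle_params(lambda, m)
      p$lt + 0.9 * p$lo * cos(p$phi)
    })
    data.frame(l_mt = l_mt, v_mt = 0, u = u,
               r = c(0.025, 0.03, 0.04, 0.038))
  }
  st <- mk_states(c(0, 0, 0, 0))
  expect_equal(knee_torque(st, lambda), 0, tolerance = 1e-12)
  # only the flexor active -> positive torque; only an extensor -> negative
  expect_gt(knee_torque(mk_states(c(0.8, 0, 0, 0)), lambda), 0)
  expect_lt(knee_torque(mk_states(c(0, 0.8, 0, 0)), lambda), 0)
  # torque is linear in each muscle's moment arm
  st2 <- mk_states(c(0.5, 0.4, 0.3, 0.2))
  st3 <- st2; st3$r[2] <- 2 * st3$r[2]
  base <- knee_torque(st2, lambda)
  only_rf <- st2; only_rf$u[-2] <- 0
  rf_part <- knee_torque(only_rf, lambda)
  expect_equal(knee_torque(st3, lambda), base + rf_part, tolerance = 1e-9)
  expect_error(knee_torque(st2[1:3, ], lambda), class = "emgknee_invalid_input")
})

test_that("forward torque series matches the scalar operation sample-wise", {
  s <- quick_subject(seed = 301, duration = 3)
  ds <- subject_dataset(s, "clean")
  out <- forward_torque(ds, s$lambda_true)
  expect_equal(nrow(out), nrow(ds))
  # naive loop-based recomputation using the scalar path, sharing the same
  # velocity estimate
  prep <- emgknee:::prepare_dataset(ds)
  idx <- c(5, 50, 150, 299)
  for (i in idx) {
    st <- data.frame(
      l_mt = sapply(knee_muscles$muscle, function(m) prep$lmt[[m]][i]),
      v_mt = sapply(knee_muscles$muscle, function(m) prep$vmt[[m]][i]),
      u = sapply(knee_muscles$muscle, function(m) prep$u[[m]][i]),
      r = sapply(knee_muscles$muscle, function(m) prep$r[[m]][i]))
    expect_equal(out$tau[i], knee_torque(st, s$lambda_true),
                 tolerance = 1e-12)
  }
  # constant geometry + zero EMG -> identically zero torque
  n <- 50
  flat <- tibble::tibble(time_s = seq(0, 0.49, 0.01))
  for (m in knee_muscles$muscle) {
    p <- emgknee:::muscle_params(s$lambda_true, m)
    flat[[paste0("u_", m)]] <- 0
    flat[[paste0("lmt_", m)]] <- p$lt + p$lo * cos(p$phi) * 0.98
    flat[[paste0("r_", m)]] <- 0.03
  }
  expect_equal(forward_torque(flat, s$lambda_true)$tau, rep(0, 50))
})

test_that("forward model regenerates the generator's noise-free torque", {
  s <- quick_subject(seed = 77, duration = 5)
  ds <- subject_dataset(s, "clean")
  regen <- forward_torque(ds, s$lambda_true)$tau
  expect_lt(max(abs(regen - ds$tau_clean)), 1e-9)
  expect_equal(torque_objective(s$lambda_true, ds), 0, tolerance = 1e-18)
})
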