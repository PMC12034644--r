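test_that("Sobol' points are uniform, dyadically balanced and seeded", {
  set.seed(9)
  X <- sobol_points(2^10, 5)
  expect_true(all(X >= 0 & X < 1))
  expect_lt(max(abs(colMeans(X) - 0.5)), 0.01)
  # unscrambled sequence stratifies each dimension perfectly over dyadic bins
  U <- sobol_points(2^8, 4, scramble = FALSE)
  for (j in 1:4) {
    counts <- tabulate(floor(U[, j] * 16) + 1, nbins = 16)
    expect_true(all(counts == 2^8 / 16))
  }
  # scrambling is reproducible under a seed
  set.seed(11); X1 <- sobol_points(64, 3)
  set.seed(11); X2 <- sobol_points(64, 3)
  expect_identical(X1, X2)
})

test_that("design construction builds A, B and the pick matrices", {
  b <- unit_box(4)
  d <- sobol_design(b, P = 128, seed = 3)
  expect_equal(dim(d$A), c(128, 4))
  expect_true(all(d$A >= 0 & d$A <= 1))
  expect_false(isTRUE(all.equal(d$A, d$B)))   # independent streams
  ab2 <- design_pick(d, 2)
  expect_equal(ab2[, -2], d$A[, -2])
  expect_equal(ab2[, 2], d$B[, 2])
  ba2 <- design_pick(d, 2, from = "B")
  expect_equal(ba2[, 2], d$A[, 2])
  baij <- design_pick_pair(d, 1, 3)
  expect_equal(baij[, c(1, 3)], d$A[, c(1, 3)])
  expect_equal(baij[, c(2, 4)], d$B[, c(2, 4)])
  expect_error(design_pick_pair(d, 2, 2), class = "emgknee_invalid_input")
  # d = 1: AB(1) is exactly B
  d1 <- sobol_design(unit_box(1), P = 64, seed = 1)
  expect_equal(design_pick(d1, 1), d1$B)
  # non power of two is rounded up with a warning
  expect_warning(dw <- sobol_design(b, P = 100, seed = 2), "power of two")
  expect_equal(dw$P, 128)
})

test_that("estimators recover analytic indices on standard test functions", {
  # additive function: no interactions, S1 ~ ST
  b <- unit_box(2)
  d <- sobol_design(b, 2^12, seed = 5)
  add <- function(X) X[, 1] + X[, 2]
  s <- sobol_analyze(add, d)
  expect_equal(s$S1, c(0.5, 0.5), tolerance = 0.05)
  expect_lt(max(abs(s$ST - s$S1)), 0.02)
  expect_lt(abs(s$IN), 0.02)
  # f(x) = x1: all variance on the first input
  s1only <- sobol_analyze(function(X) X[, 1], d)
  expect_equal(s1only$S1, c(1, 0), tolerance = 0.02)
  # product function: analytic Var = 7/144, V1 = V2 = 3/144, V12 = 1/144
  dp <- sobol_design(b, 2^13, seed = 6)
  sp <- sobol_analyze(function(X) X[, 1] * X[, 2], dp, second_order = "all")
  expect_equal(sp$S1, c(3 / 7, 3 / 7), tolerance = 0.03)
  expect_true(all(sp$ST > sp$S1))
  expect_equal(sp$S2$S2, 1 / 7, tolerance = 0.03)
  # constant output has no variance to decompose
  expect_error(sobol_analyze(function(X) rep(2, nrow(X)), d),
               class = "emgknee_numeric_error")
})

test_that("index bookkeeping identities hold exactly", {
  d <- sobol_design(unit_box(3), 2^11, seed = 8)
  f <- function(X) sin(X[, 1]) + X[, 2]^2 * X[, 3]
  s <- sobol_analyze(f, d)
  expect_equal(s$INi, s$ST - s$S1, tolerance = 1e-12)
  expect_equal(s$IN, 1 - sum(s$S1), tolerance = 1e-12)
  expect_true(all(s$ST >= s$S1 - 3 / sqrt(s$P)))
})

test_that("interaction screening gates pairs on IN and INi", {
  base <- list(S1 = rep(0.2, 4), ST = rep(0.21, 4))
  expect_equal(nrow(interaction_screen(base)), 0)    # IN small, INi small
  # strong interactions on parameters 1 and 3 only
  res <- list(S1 = c(0.1, 0.3, 0.1, 0.2), ST = c(0.3, 0.33, 0.32, 0.23))
  scr <- interaction_screen(res, threshold = 0.05, in_gate = 0.1)
  expect_equal(scr$i, 1)
  expect_equal(scr$j, 3)
  # threshold 1 excludes everything (INi <= 1)
  expect_equal(nrow(interaction_screen(res, threshold = 1)), 0)
  # four flagged parameters give all six pairs
  res4 <- list(S1 = c(0.1, 0.1, 0.1, 0.1, 0.2),
               ST = c(0.2, 0.2, 0.2, 0.2, 0.21))
  scr4 <- interaction_screen(res4, threshold = 0.05, in_gate = 0.1)
  expect_equal(nrow(scr4), 6)
  expect_setequal(unique(c(scr4$i, scr4$j)), 1:4)
})

test_that("disturbance functional is zero at the optimum and matches the MSE objective", {
  s <- quick_subject(seed = 207, duration = 4)
  ds <- subject_dataset(s, "clean")
  f <- output_functional(ds, s$lambda_true)
  expect_equal(f(unclass(s$lambda_true))[1], 0, tolerance = 1e-18)
  lam2 <- draw_lambda(seed = 3)
  # identity with the identification objective when the reference torque is
  # regenerated from the optimum
  ds2 <- ds
  ds2$tau_ref <- forward_torque(ds, s$lambda_true)$tau
  expect_equal(f(unclass(lam2))[1], torque_objective(lam2, ds2),
               tolerance = 1e-12)
  expect_true(all(f(rbind(unclass(lam2), unclass(draw_lambda(seed = 9)))) >= 0))
})

test_that("model sensitivity indices are within estimator range", {
  s <- quick_subject(seed = 208, duration = 4)
  ds <- subject_dataset(s, "clean")
  f <- output_functional(ds, s$lambda_true)
  des <- sobol_design(make_bounds(), P = 1024, seed = 4)
  sens <- sobol_analyze(f, des, second_order = "none")
  eps <- 3 / sqrt(sens$P)
  expect_true(all(sens$S1 >= -eps & sens$S1 <= 1 + eps))
  expect_true(all(sens$ST >= -eps & sens$ST <= 1 + eps))
  expect_true(all(sens$ST >= sens$S1 - eps))
})

test_that("parameters of a zero-moment-arm muscle are dead in the output", {
  s <- quick_subject(seed = 209, duration = 4)
  ds <- subject_dataset(s, "clean")
  ds$r_bf <- 0                      # BF can no longer transmit torque
  f <- output_functional(ds, s$lambda_true)
  # Y is exactly zero for changes confined to BF's own parameters
  lam2 <- unclass(s$lambda_true)
  bf_idx <- grep("_bf$", param_names())
  lam2[bf_idx] <- unclass(draw_lambda(seed = 14))[bf_idx]
  expect_equal(f(lam2)[1], 0, tolerance = 1e-18)
  # and the estimated total-effect indices of those parameters vanish
  des <- sobol_design(make_bounds(), P = 512, seed = 6)
  sens <- sobol_analyze(f, des, second_order = "none")
  expect_lt(max(abs(sens$ST[bf_idx])), 1e-10)
})
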