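# build a synthetic pair of sensitivity results with known structure
fake_sens <- function(S1, ST, pairs = NULL) {
  s2 <- if (is.null(pairs)) {
    tibble::tibble(i = integer(0), j = integer(0), S2 = numeric(0))
  } else {
    pairs
  }
  structure(list(terms = param_names(), S1 = S1, ST = ST, INi = ST - S1,
                 IN = 1 - sum(S1), S2 = s2, f0 = 1, varY = 1, P = 1024,
                 bounds = make_bounds()), class = "emg_sobol")
}

test_that("parameter ranking averages subjects and breaks ties by index", {
  ST1 <- rep(0.01, 26); ST1[9] <- 0.9
  ST2 <- rep(0.01, 26); ST2[9] <- 0.8
  sens <- list(fake_sens(ST1 * 0.9, ST1), fake_sens(ST2 * 0.9, ST2))
  lams <- list(draw_lambda(seed = 1), draw_lambda(seed = 2))
  plan <- rank_parameters(sens, lams)
  expect_equal(plan$ranking[1], 9)
  # all remaining indices tie at 0.01 -> ranking stays in index order
  expect_equal(plan$ranking[-1], setdiff(1:26, 9))
  # fixed values are the elementwise mean of the identified vectors
  expect_equal(unclass(plan$fixed_values),
               (unclass(lams[[1]]) + unclass(lams[[2]])) / 2)
  expect_error(rank_parameters(list(), lams), class = "emgknee_invalid_input")
})

test_that("screened interaction pairs define the mandatory set", {
  ST <- rep(0.05, 26)
  pairs <- tibble::tibble(i = c(9, 16), j = c(25, 18), S2 = c(0.2, 0.1))
  sens <- list(fake_sens(ST * 0.5, ST, pairs))
  plan <- rank_parameters(sens, list(draw_lambda(seed = 3)))
  expect_equal(plan$mandatory, c(9, 16, 18, 25))
  # minimum q is the mandatory-set size
  expect_equal(free_set(plan, 4), c(9, 16, 18, 25))
  expect_error(free_set(plan, 3), class = "emgknee_config_error")
  # weak pairs (S2 below threshold) do not force parameters in
  weak <- tibble::tibble(i = 2L, j = 3L, S2 = 0.01)
  plan2 <- rank_parameters(list(fake_sens(ST * 0.5, ST, weak)),
                           list(draw_lambda(seed = 3)))
  expect_equal(plan2$mandatory, integer(0))
})

test_that("free sets are nested and grow by descending rank", {
  ST <- seq(26, 1, length.out = 26) / 26    # rank = index order
  pairs <- tibble::tibble(i = 20L, j = 24L, S2 = 0.3)
  plan <- rank_parameters(list(fake_sens(ST * 0.8, ST, pairs)),
                          list(draw_lambda(seed = 5)))
  expect_equal(plan$mandatory, c(20, 24))
  qs <- c(2, 5, 10, 16, 26)
  sets <- lapply(qs, function(q) free_set(plan, q))
  for (k in seq_len(length(qs) - 1)) {
    expect_true(all(sets[[k]] %in% sets[[k + 1]]))
    expect_length(sets[[k]], qs[k])
  }
  # beyond the mandatory pair, the set fills with the top-ranked parameters
  expect_equal(sets[[2]], sort(c(20, 24, 1, 2, 3)))
  expect_equal(sets[[5]], 1:26)
})

test_that("precision ratio follows its definition", {
  expect_equal(precision_ratio(1, 1), 1)
  expect_equal(precision_ratio(0.8, 1.0), 0.8)
  expect_equal(precision_ratio(0.6376, 0.797), 0.8, tolerance = 1e-3)
  expect_warning(r <- precision_ratio(0.5, 0),
                 class = "emgknee_undefined_ratio")
  expect_equal(r, Inf)
  expect_error(precision_ratio(-1, 1), class = "emgknee_invalid_input")
})

test_that("reduced identification frees exactly the planned set", {
  s <- quick_subject(seed = 501, duration = 4)
  ds <- subject_dataset(s, "clean")
  ST <- rep(0.01, 26)
  fo_idx <- grep("^fo_", param_names())
  ST[fo_idx] <- c(0.9, 0.8, 0.7, 0.6)
  plan <- rank_parameters(list(fake_sens(ST * 0.9, ST)),
                          list(s$lambda_true))
  fit <- reduced_identify(ds, plan, q = 4, config = quick_ga(seed = 3))
  expect_equal(which(fit$free_mask), sort(fo_idx))
  # fixed parameters pass through the plan values (here: the truth)
  expect_equal(unclass(fit$lambda_opt)[-fo_idx],
               unclass(s$lambda_true)[-fo_idx])
  # q = 26 frees everything
  fit26 <- reduced_identify(ds, plan, q = 26,
                            config = quick_ga(seed = 3, max_generations = 5))
  expect_true(all(fit26$free_mask))
})

test_that("a reduced model containing the truth is recovered at small q", {
  # ground truth differs from the plan's fixed values only in the four
  # maximum forces, so a perfect model exists in the q = 4 space
  s <- quick_subject(seed = 502, duration = 6)
  ds <- subject_dataset(s, "clean")
  ST <- rep(0.01, 26)
  fo_idx <- grep("^fo_", param_names())
  ST[fo_idx] <- c(0.9, 0.8, 0.7, 0.6)
  plan <- rank_parameters(list(fake_sens(ST * 0.9, ST)),
                          list(s$lambda_true))
  fit <- reduced_identify(ds, plan, q = 4,
                          config = quick_ga(seed = 11, population_size = 80,
                                            max_generations = 150))
  expect_lte(fit$metrics$nrmse_pct, 5)
})

test_that("the q sweep reports ratios and parameter reductions per subject", {
  # mild torque noise keeps RMSEs away from zero so ratios are finite
  s <- quick_subject(seed = 503, duration = 4,
                     noise = list(torque_rel_sd = 0.03, torque_abs_sd = 0,
                                  emg_carrier_sd = 0.05))
  ds <- subject_dataset(s, "clean")
  ST <- rep(0.01, 26); ST[grep("^fo_", param_names())] <- 0.5
  plan <- rank_parameters(list(fake_sens(ST * 0.9, ST)),
                          list(s$lambda_true))
  full <- ga_identify(ds, config = quick_ga(seed = 4, population_size = 40,
                                            max_generations = 40))
  rep1 <- q_sweep(list(S1 = ds), plan, list(full), q_grid = c(4, 16),
                  config = quick_ga(seed = 1, crossover = "sbx",
                                    mutation = "polynomial",
                                    population_size = 40,
                                    max_generations = 40),
                  seed = 9)
  expect_equal(nrow(rep1$results), 2)
  expect_true(all(rep1$results$R > 0))
  expect_equal(rep1$results$reduction_pct[rep1$results$q == 16],
               100 * (26 - 16) / 26, tolerance = 1e-9)
  # deterministic regeneration from the same seed
  rep2 <- q_sweep(list(S1 = ds), plan, list(full), q_grid = c(4, 16),
                  config = quick_ga(seed = 1, crossover = "sbx",
                                    mutation = "polynomial",
                                    population_size = 40,
                                    max_generations = 40),
                  seed = 9)
  expect_equal(rep1$results, rep2$results)
  gl <- glance(rep1)
  expect_equal(nrow(gl), 2)
  expect_true("median_R" %in% names(gl))
})
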