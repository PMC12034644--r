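test_that("geometry follows the tendon-excursion principle", {
  cfg <- synth_config()
  theta <- seq(0.4, 1.4, length.out = 201)
  g <- make_geometry(theta, cfg$geometry)
  # constant angle gives constant geometry
  gc <- make_geometry(rep(0.9, 10), cfg$geometry)
  for (col in names(gc)) expect_equal(stats::sd(gc[[col]]), 0)
  # linear length-angle relation: moment arm equals |slope| exactly
  glin <- make_geometry(theta, list(bf = c(0.46, -0.028, 0),
                                    rf = c(0.40, 0.042, 0),
                                    vl = c(0.215, 0.048, 0),
                                    vm = c(0.175, 0.045, 0)))
  expect_equal(glin$r_bf, rep(0.028, 201))
  expect_equal(glin$r_rf, rep(0.042, 201))
  # quadratic case: analytic moment arm matches numerical differentiation
  dth <- theta[2] - theta[1]
  num <- abs((g$lmt_rf[3:201] - g$lmt_rf[1:199]) / (2 * dth))
  expect_equal(g$r_rf[2:200], num, tolerance = 1e-6)
  # flexor shortens while extensors lengthen with flexion
  expect_lt(g$lmt_bf[201], g$lmt_bf[1])
  expect_gt(g$lmt_rf[201], g$lmt_rf[1])
  # impossible tendon length is a config error
  expect_error(make_geometry(theta, cfg$geometry,
                             lt = c(bf = 0.5, rf = 0.1, vl = 0.1, vm = 0.1)),
               class = "emgknee_config_error")
})

test_that("synthetic EMG round-trips through the signal chain", {
  rate <- 2000
  t <- seq(0, 6, by = 1 / rate)
  # silence stays silent
  x0 <- make_emg(rep(0, length(t)), rate, seed = 2)
  expect_equal(max(abs(x0)), 0)
  # full drive recovers a near-unit normalized envelope
  x1 <- make_emg(rep(1, length(t)), rate, seed = 3)
  env1 <- emg_envelope(x1, rate)
  u1 <- mvc_normalize(env1, mvc_peak(x1, rate))
  core <- seq(rate, length(t) - rate)
  expect_gt(mean(u1[core]), 0.8)
  expect_lte(max(u1), 1)
  # burst-train drive correlates strongly after the full pipeline
  a <- burst <- 0.02 + 0.6 * pmax(sin(2 * pi * t / 3), 0)^2
  x <- make_emg(a, rate, seed = 4)
  u <- mvc_normalize(emg_envelope(x, rate), mvc_peak(x1, rate))
  expect_gt(stats::cor(u[core], a[core]), 0.9)
})

test_that("subjects are deterministic and reproducible from their seed", {
  s1 <- make_subject(synth_config(seed = 42, duration = 3))
  s2 <- make_subject(synth_config(seed = 42, duration = 3))
  expect_identical(s1$dataset, s2$dataset)
  expect_identical(s1$emg_raw, s2$emg_raw)
  expect_identical(unclass(s1$lambda_true), unclass(s2$lambda_true))
  s3 <- make_subject(synth_config(seed = 43, duration = 3))
  expect_false(identical(unclass(s1$lambda_true), unclass(s3$lambda_true)))
})

test_that("noise settings act as specified", {
  s0 <- make_subject(synth_config(seed = 9, duration = 3))
  expect_identical(s0$dataset$tau_ref, s0$dataset$tau_clean)
  sn <- make_subject(synth_config(seed = 9, duration = 3,
                                  noise = list(torque_rel_sd = 0.05,
                                               torque_abs_sd = 0,
                                               emg_carrier_sd = 0.05)))
  expect_identical(sn$dataset$tau_clean, s0$dataset$tau_clean)
  rel <- (sn$dataset$tau_ref - sn$dataset$tau_clean) /
    pmax(abs(sn$dataset$tau_clean), 1e-12)
  expect_lt(abs(stats::sd(rel) - 0.05), 0.01)
})

test_that("muscle roles show through the torque sign end to end", {
  # drive one muscle at a time and audit the torque sign convention
  base_act <- list(baseline = 0, period = 4,
                   bf = c(1, 1.2, 0), rf = c(1, 1.2, 0),
                   vl = c(1, 1.2, 0), vm = c(1, 1.2, 0))
  for (m in knee_muscles$muscle) {
    act <- base_act
    act[[m]][3] <- 0.7
    s <- make_subject(synth_config(seed = 5, duration = 4, activation = act))
    tau_at_burst <- s$dataset$tau_clean[abs(s$dataset$time_s - 1) < 0.2]
    if (m == "bf") {
      expect_gt(min(tau_at_burst), 0)
    } else {
      expect_lt(max(tau_at_burst), 0)
    }
  }
})

test_that("generated truths sit strictly inside the generic bounds", {
  b <- make_bounds()
  for (seed in c(1, 7, 19)) {
    s <- make_subject(synth_config(seed = seed, duration = 2))
    lam <- unclass(s$lambda_true)
    expect_true(all(lam > b$lower & lam < b$upper))
  }
})

test_that("pipeline-processed streams approximate the clean dataset", {
  s <- make_subject(synth_config(seed = 33, duration = 8))
  clean <- subject_dataset(s, "clean")
  piped <- subject_dataset(s, "pipeline")
  core <- piped$time_s > 1 & piped$time_s < max(piped$time_s) - 1
  for (m in knee_muscles$muscle) {
    u_p <- piped[[paste0("u_", m)]][core]
    u_c <- stats::approx(clean$time_s, clean[[paste0("u_", m)]],
                         piped$time_s[core])$y
    expect_gt(stats::cor(u_p, u_c), 0.9)
    # geometry interpolates near-exactly
    l_p <- piped[[paste0("lmt_", m)]][core]
    l_c <- stats::approx(clean$time_s, clean[[paste0("lmt_", m)]],
                         piped$time_s[core])$y
    expect_lt(max(abs(l_p - l_c)), 1e-4)
  }
})

test_that("subject CSV round trip reproduces the analysis dataset", {
  s <- make_subject(synth_config(seed = 51, duration = 4))
  dir <- withr::local_tempdir()
  write_subject(s, dir)
  expect_true(all(file.exists(file.path(dir, c("emg.csv", "geometry.csv",
                                               "torque.csv", "truth.json")))))
  ds <- read_subject_dataset(dir)
  expect_true(all(dataset_cols <- c("time_s", paste0("u_", knee_muscles$muscle),
                                    paste0("lmt_", knee_muscles$muscle),
                                    paste0("r_", knee_muscles$muscle),
                                    "tau_ref") %in% names(ds)))
  direct <- subject_dataset(s, "pipeline")
  expect_equal(nrow(ds), nrow(direct))
  expect_equal(ds$tau_ref, direct$tau_ref, tolerance = 1e-6)
  # ground truth stored in the artifact
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(unlist(truth$lambda_true)[param_names()],
               unclass(s$lambda_true), tolerance = 1e-12,
               ignore_attr = TRUE)
})
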