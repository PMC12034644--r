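#' Synthetic-subject configuration
#'
#' Defines the study conditions a synthetic recording emulates: a suspended-
#' shank knee flexion/extension movement (smooth periodic knee angle), four
#' muscles with quadratic muscle-tendon length vs angle (moment arms by the
#' tendon-excursion principle, `r = |d l_mt / d theta|`), raised-cosine
#' activation bursts staggered across muscles so each muscle's contribution
#' is temporally distinguishable, an amplitude-modulated band-limited noise
#' model for raw sEMG at 2000 Hz, and multiplicative reference-torque noise
#' standing in for inverse-dynamics error.
#'
#' @param seed Subject seed (all streams derive split seeds from it).
#' @param duration Trial length, s.
#' @param analysis_rate,emg_rate,mocap_rate Sampling rates, Hz.
#' @param angle List: `profile` (`"sinusoid"` or `"sum_of_sines"`), `mean`,
#'   `amplitude` (rad), `period` (s).
#' @param geometry Per-muscle quadratic coefficients `c(c0, c1, c2)` of
#'   `l_mt(theta) = c0 + c1*theta + c2*theta^2` (m, rad).
#' @param activation Per-muscle burst list `c(center, width, amplitude)`
#'   (s, s, unitless), repeated each `period`, plus a small `baseline`.
#' @param noise List: `torque_rel_sd` (multiplicative reference-torque
#'   noise), `torque_abs_sd` (additive, N m), `emg_carrier_sd` (raw carrier
#'   scale, mV).
#' @param lambda_true Ground-truth [param_vector()]; `NULL` draws one
#'   uniformly from the central part of the identification box (see
#'   `margin`).
#' @param margin Fraction of each bound interval excluded on both sides when
#'   drawing `lambda_true`, so truth is never bound-clipped.
#' @param kpe Passive shape constant.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, duration = 16, analysis_rate = 100,
                         emg_rate = 2000, mocap_rate = 200,
                         angle = list(profile = "sinusoid", mean = 0.9,
                                      amplitude = 0.5, period = 4),
                         geometry = list(
                           bf = c(0.460, -0.040, 0.002),
                           rf = c(0.400, 0.042, -0.006),
                           vl = c(0.215, 0.048, -0.005),
                           vm = c(0.175, 0.045, -0.004)),
                         activation = list(
                           baseline = 0.02, period = 4,
                           bf = list(c(0.5, 1.2, 0.80), c(2.6, 0.8, 0.45)),
                           rf = list(c(1.6, 1.0, 0.50), c(3.4, 0.7, 0.28)),
                           vl = list(c(2.4, 1.1, 0.55), c(0.9, 0.7, 0.30)),
                           vm = list(c(3.2, 1.0, 0.50), c(1.3, 0.8, 0.25)),
                           cycle_mod = list(bf = c(1, 0.65, 0.85, 0.5),
                                            rf = c(0.7, 1, 0.45, 0.85),
                                            vl = c(0.9, 0.55, 1, 0.7),
                                            vm = c(0.6, 0.95, 0.75, 1))),
                         noise = list(torque_rel_sd = 0, torque_abs_sd = 0,
                                      emg_carrier_sd = 0.05),
                         lambda_true = NULL, margin = 0.25, kpe = 5) {
  cfg <- list(seed = seed, duration = duration, analysis_rate = analysis_rate,
              emg_rate = emg_rate, mocap_rate = mocap_rate, angle = angle,
              geometry = geometry, activation = activation, noise = noise,
              lambda_true = lambda_true, margin = margin, kpe = kpe)
  structure(cfg, class = "synth_config")
}

#' Draw a ground-truth parameter vector inside the identification box
#'
#' Uniform on the central `(1 - 2*margin)` fraction of each bound interval,
#' so identification of the truth is never clipped by the box.
#'
#' @param bounds A [make_bounds()] object.
#' @param margin Excluded fraction on each side.
#' @param seed RNG seed.
#' @return A [param_vector()].
#' @export
draw_lambda <- function(bounds = make_bounds(), margin = 0.25, seed = NULL) {
  rng <- bounds$upper - bounds$lower
  with_seed(seed, {
    param_vector(bounds$lower + rng * (margin + (1 - 2 * margin) *
                                         stats::runif(26)))
  })
}

# knee-angle trajectory, rad
angle_series <- function(t, angle) {
  th <- switch(angle$profile,
    sinusoid = angle$mean + angle$amplitude * sin(2 * pi * t / angle$period),
    sum_of_sines = angle$mean +
      angle$amplitude * (0.7 * sin(2 * pi * t / angle$period) +
                         0.3 * sin(2 * pi * t * 2.3 / angle$period + 1)),
    abort_config(paste("unknown angle profile:", angle$profile)))
  if (any(th < 0 | th > 2.3)) {
    abort_config("knee angle profile leaves the physiologic range [0, 2.3] rad")
  }
  th
}

#' Muscle geometry from a knee-angle trajectory
#'
#' Muscle-tendon lengths are quadratic in the knee angle; moment arms follow
#' from the tendon-excursion principle, `r = |d l_mt / d theta|`, evaluated
#' analytically. Flexor and extensor length polynomials have opposite slope
#' signs so flexion shortens the flexor and lengthens the extensors.
#'
#' @param theta Knee-angle series, rad.
#' @param geometry Per-muscle coefficient list (see [synth_config()]).
#' @param lt Named vector (or NULL) of tendon lengths used to verify
#'   `l_mt > lt` everywhere; violation is a config error.
#' @return Tibble with `lmt_<muscle>` and `r_<muscle>` columns.
#' @export
make_geometry <- function(theta, geometry, lt = NULL) {
  out <- tibble::tibble(.rows = length(theta))
  for (m in knee_muscles$muscle) {
    cf <- geometry[[m]]
    lmt <- cf[1] + cf[2] * theta + cf[3] * theta^2
    if (!is.null(lt) && any(lmt <= lt[[m]])) {
      abort_config(sprintf(
        "geometry for %s gives l_mt <= tendon length (min %.3f <= %.3f)",
        m, min(lmt), lt[[m]]))
    }
    out[[paste0("lmt_", m)]] <- lmt
    out[[paste0("r_", m)]] <- abs(cf[2] + 2 * cf[3] * theta)
  }
  out
}

# one raised-cosine burst centred at `center` with support `width`
raised_cosine <- function(t, center, width) {
  ph <- t - center
  ifelse(abs(ph) < width / 2, 0.5 * (1 + cos(2 * pi * ph / width)), 0)
}

# burst train for one muscle: each cycle repeats the muscle's bursts, with a
# deterministic cycle-to-cycle amplitude modulation so repeated contractions
# vary the way natural repetitions do (and keep the excitation persistent)
burst_train <- function(t, bursts, period, baseline = 0, cycle_mod = 1) {
  if (!is.list(bursts)) bursts <- list(bursts)
  n_cycles <- ceiling((max(t) + period) / period)
  a <- numeric(length(t))
  for (k in seq_len(n_cycles)) {
    mod_k <- cycle_mod[((k - 1) %% length(cycle_mod)) + 1]
    for (b in bursts) {
      a <- a + mod_k * b[3] * raised_cosine(t, b[1] + (k - 1) * period, b[2])
    }
  }
  pmin(baseline + a, 1)
}

# target activations for all muscles on a time grid
activation_profiles <- function(t, act) {
  cm <- act$cycle_mod
  out <- lapply(knee_muscles$muscle, function(m) {
    burst_train(t, act[[m]], act$period, act$baseline,
                cycle_mod = if (is.null(cm[[m]])) 1 else cm[[m]])
  })
  names(out) <- knee_muscles$muscle
  out
}

#' Synthesize a raw sEMG-like trace
#'
#' Zero-mean Gaussian noise band-limited to 20-450 Hz, amplitude-modulated
#' by the supplied envelope, and scaled so that a unit modulator yields a
#' unit linear envelope (the carrier is self-calibrated against the analysis
#' envelope chain). Seeded and deterministic.
#'
#' @param modulator Envelope modulation in \[0, 1\] on the EMG time grid.
#' @param emg_rate Sampling rate, Hz.
#' @param seed RNG seed.
#' @param carrier_sd Raw carrier standard deviation (output scale, mV).
#' @return Numeric trace of `length(modulator)` samples.
#' @export
make_emg <- function(modulator, emg_rate, seed = NULL, carrier_sd = 0.05) {
  if (any(modulator < 0 | modulator > 1.0000001)) {
    abort_invalid("EMG modulator must lie in [0, 1]")
  }
  n <- length(modulator)
  with_seed(seed, {
    carrier <- emg_bandpass(stats::rnorm(n, 0, carrier_sd), emg_rate)
    env <- emg_envelope(carrier, emg_rate)
    # self-calibration: unit modulator -> unit envelope (interior mean)
    core <- seq.int(max(1, n %/% 10), n - max(1, n %/% 10) + 1)
    carrier <- carrier / mean(env[core])
    carrier * modulator
  })
}

#' Generate a complete synthetic subject
#'
#' Produces, from one ground-truth parameter vector: the knee-angle
#' trajectory; exact muscle geometry on the analysis grid (plus a 200 Hz
#' motion-capture-like stream); per-muscle target activations inverted
#' through the EMG-to-activation nonlinearity so the exact normalized EMG
#' `u(t)` is known; the noise-free reference torque from the forward model;
#' a noisy reference torque; raw 2000 Hz sEMG-like traces whose envelopes
#' recover `u(t)`; and per-muscle MVC trials for normalization.
#'
#' @param cfg A [synth_config()].
#' @param bounds Identification bounds the truth is drawn within.
#' @return An object of class `synthetic_subject` with elements
#'   `lambda_true`, `dataset` (aligned tibble with exact `u_*`, `lmt_*`,
#'   `r_*`, noisy `tau_ref` and noise-free `tau_clean`), `emg_raw`,
#'   `geometry_mocap`, `torque`, `mvc_peaks`, `theta`, `config`.
#' @export
make_subject <- function(cfg = synth_config(), bounds = make_bounds()) {
  lambda <- if (is.null(cfg$lambda_true)) {
    draw_lambda(bounds, cfg$margin, split_seed(cfg$seed, "lambda"))
  } else {
    param_vector(cfg$lambda_true)
  }
  lt <- vapply(knee_muscles$muscle,
               function(m) muscle_params(lambda, m)$lt, numeric(1))
  A_true <- unclass(lambda)[["A"]]

  # subject-consistent geometry: anchor each muscle-tendon length so the
  # fiber sits at its optimal length at the mid-range knee angle (as a
  # scaled musculoskeletal model would); the configured coefficients supply
  # the angle dependence (hence the moment arms)
  geometry <- cfg$geometry
  th_mid <- cfg$angle$mean
  for (m in knee_muscles$muscle) {
    p <- muscle_params(lambda, m)
    cf <- geometry[[m]]
    cf[1] <- p$lt + p$lo * cos(p$phi) - cf[2] * th_mid - cf[3] * th_mid^2
    geometry[[m]] <- cf
  }

  # analysis-grid streams (exact)
  t_a <- seq(0, cfg$duration, by = 1 / cfg$analysis_rate)
  theta <- angle_series(t_a, cfg$angle)
  geom <- make_geometry(theta, geometry, lt)
  a_tgt <- activation_profiles(t_a, cfg$activation)
  ds <- tibble::tibble(time_s = t_a)
  for (m in knee_muscles$muscle) {
    ds[[paste0("u_", m)]] <- activation_inverse(a_tgt[[m]], A_true)
  }
  ds <- dplyr::bind_cols(ds, geom)
  tau_clean <- forward_torque(ds, lambda, kpe = cfg$kpe)$tau
  noise <- cfg$noise
  tau_ref <- with_seed(split_seed(cfg$seed, "torque"), {
    e_rel <- if (noise$torque_rel_sd > 0) {
      stats::rnorm(length(tau_clean), 0, noise$torque_rel_sd)
    } else 0
    e_abs <- if (noise$torque_abs_sd > 0) {
      stats::rnorm(length(tau_clean), 0, noise$torque_abs_sd)
    } else 0
    tau_clean * (1 + e_rel) + e_abs
  })
  ds$tau_ref <- tau_ref
  ds$tau_clean <- tau_clean

  # motion-capture-like geometry stream
  t_m <- seq(0, cfg$duration, by = 1 / cfg$mocap_rate)
  geom_m <- make_geometry(angle_series(t_m, cfg$angle), geometry, lt)
  geom_m <- dplyr::bind_cols(tibble::tibble(time_s = t_m), geom_m)

  # raw sEMG-like traces (exact u evaluated on the EMG grid)
  t_e <- seq(0, cfg$duration, by = 1 / cfg$emg_rate)
  a_e <- activation_profiles(t_e, cfg$activation)
  emg <- tibble::tibble(time_s = t_e)
  mvc_peaks <- numeric(4); names(mvc_peaks) <- knee_muscles$muscle
  for (m in knee_muscles$muscle) {
    u_e <- activation_inverse(a_e[[m]], A_true)
    emg[[paste0("emg_", m)]] <- make_emg(u_e, cfg$emg_rate,
                                         split_seed(cfg$seed, paste0("emg_", m)),
                                         noise$emg_carrier_sd)
    mvc_trace <- make_emg(rep(1, 2 * cfg$emg_rate), cfg$emg_rate,
                          split_seed(cfg$seed, paste0("mvc_", m)),
                          noise$emg_carrier_sd)
    mvc_peaks[m] <- mvc_peak(mvc_trace, cfg$emg_rate)
  }

  structure(list(
    lambda_true = lambda,
    dataset = ds,
    emg_raw = emg,
    geometry_mocap = geom_m,
    torque = tibble::tibble(time_s = t_a, tau_ref = tau_ref),
    mvc_peaks = mvc_peaks,
    theta = tibble::tibble(time_s = t_a, theta = theta),
    config = cfg
  ), class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject: %.1f s at %.0f Hz, seed %d>\n",
              x$config$duration, x$config$analysis_rate, x$config$seed))
  cat(sprintf("  torque range %.2f .. %.2f N m (noise rel sd %.3g)\n",
              min(x$dataset$tau_clean), max(x$dataset$tau_clean),
              x$config$noise$torque_rel_sd))
  invisible(x)
}

#' Aligned analysis dataset of a synthetic subject
#'
#' `source = "clean"` uses the generator's exact normalized EMG (the
#' noise-free study condition); `source = "pipeline"` runs the full signal
#' chain instead: raw EMG to envelope, MVC normalization, resampling of the
#' motion-capture geometry, all synchronized onto the analysis grid.
#'
#' @param subject A [make_subject()] result.
#' @param source `"clean"` or `"pipeline"`.
#' @return Aligned tibble ready for [ga_identify()] / [forward_torque()].
#' @export
subject_dataset <- function(subject, source = c("clean", "pipeline")) {
  source <- match.arg(source)
  if (source == "clean") {
    return(subject$dataset)
  }
  rate <- subject$config$emg_rate
  u_df <- tibble::tibble(time_s = subject$emg_raw$time_s)
  for (m in knee_muscles$muscle) {
    env <- emg_envelope(subject$emg_raw[[paste0("emg_", m)]], rate)
    u_df[[paste0("u_", m)]] <- mvc_normalize(env, subject$mvc_peaks[[m]])
  }
  ds <- synchronize(u_df, subject$geometry_mocap,
                    subject$config$analysis_rate)
  ds$tau_ref <- stats::approx(subject$torque$time_s, subject$torque$tau_ref,
                              xout = ds$time_s, rule = 2)$y
  ds
}

#' Validation-trial configuration for an existing subject
#'
#' Same ground truth and geometry, different movement realization: the
#' activation bursts are shifted within the cycle, the trial is shorter and
#' all noise streams are re-seeded, giving an out-of-sample trial for
#' validation metrics.
#'
#' @param subject A [make_subject()] result.
#' @param duration Validation trial length, s.
#' @return A `synth_config` whose `lambda_true` equals the subject's truth.
#' @export
validation_config <- function(subject, duration = 8) {
  cfg <- subject$config
  cfg$duration <- duration
  cfg$seed <- split_seed(cfg$seed, "validation")
  shift <- cfg$activation$period * 0.45
  for (m in knee_muscles$muscle) {
    bursts <- cfg$activation[[m]]
    if (!is.list(bursts)) bursts <- list(bursts)
    cfg$activation[[m]] <- lapply(bursts, function(b) {
      c((b[1] + shift) %% cfg$activation$period, b[2] * 0.85, b[3])
    })
  }
  cfg$lambda_true <- subject$lambda_true
  cfg
}

#' Write a synthetic subject's streams to a directory
#'
#' Emits `emg.csv` (2000 Hz raw EMG), `geometry.csv` (200 Hz muscle-tendon
#' lengths and moment arms), `torque.csv` (reference torque at the analysis
#' rate) and `truth.json` (ground-truth parameters, MVC peaks, seed).
#'
#' @param subject A [make_subject()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_timeseries_csv(subject$emg_raw, file.path(dir, "emg.csv"))
  write_timeseries_csv(subject$geometry_mocap, file.path(dir, "geometry.csv"))
  write_timeseries_csv(subject$torque, file.path(dir, "torque.csv"))
  jsonlite::write_json(list(
    lambda_true = as.list(unclass(subject$lambda_true)),
    mvc_peaks = as.list(subject$mvc_peaks),
    seed = subject$config$seed,
    analysis_rate = subject$config$analysis_rate,
    kpe = subject$config$kpe
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic subject directory back into an aligned dataset
#'
#' Runs the signal chain on the stored streams: envelopes the raw EMG,
#' normalizes by the stored MVC peaks, and synchronizes EMG, geometry and
#' torque onto the analysis grid.
#'
#' @param dir Directory written by [write_subject()].
#' @return Aligned analysis tibble.
#' @export
read_subject_dataset <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  emg <- read_timeseries_csv(file.path(dir, "emg.csv"),
                             paste0("emg_", knee_muscles$muscle))
  geom <- read_timeseries_csv(file.path(dir, "geometry.csv"),
                              c(paste0("lmt_", knee_muscles$muscle),
                                paste0("r_", knee_muscles$muscle)))
  torque <- read_timeseries_csv(file.path(dir, "torque.csv"), "tau_ref")
  rate <- 1 / mean(diff(emg$time_s))
  u_df <- tibble::tibble(time_s = emg$time_s)
  for (m in knee_muscles$muscle) {
    env <- emg_envelope(emg[[paste0("emg_", m)]], rate)
    u_df[[paste0("u_", m)]] <- mvc_normalize(env, truth$mvc_peaks[[m]])
  }
  ds <- synchronize(u_df, geom, truth$analysis_rate)
  ds$tau_ref <- stats::approx(torque$time_s, torque$tau_ref, xout = ds$time_s,
                              rule = 2)$y
  ds
}
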