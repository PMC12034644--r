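#' Mean-squared torque error objective
#'
#' The identification objective: the mean squared difference between the
#' model torque under `lambda` and the reference torque of the dataset,
#' `(1/N) * sum((tau_n - tau_ref_n)^2)`. Finite for any parameter vector in
#' the search box (degenerate geometry is floored, never NaN).
#'
#' @param lambda A [param_vector()].
#' @param data Aligned dataset with a `tau_ref` column (or a prepared
#'   dataset).
#' @param kpe Passive shape constant.
#' @return Mean squared error, (N m)^2.
#' @export
torque_objective <- function(lambda, data, kpe = 5) {
  prep <- if (inherits(data, "emgknee_prep")) data else prepare_dataset(data)
  if (is.null(prep$tau_ref)) abort_schema("dataset has no tau_ref column")
  if (any(!is.finite(prep$tau_ref))) abort_data("tau_ref contains non-finite values")
  tau <- forward_torque_matrix(prep, matrix(unclass(param_vector(lambda)),
                                            nrow = 1), kpe)
  mean((as.numeric(tau) - prep$tau_ref)^2)
}

# batch objective for a chromosome matrix (pop x 26) -> MSE per chromosome
objective_batch <- function(prep, L, kpe = 5) {
  tau <- forward_torque_matrix(prep, L, kpe)
  ref <- matrix(prep$tau_ref, nrow(tau), ncol(tau), byrow = TRUE)
  rowMeans((tau - ref)^2)
}

#' Genetic-algorithm settings
#'
#' Defaults follow the identification protocol: floating-point chromosomes,
#' tournament selection (size 3), elitism of 2, and a hard cap of 1000
#' generations. Full-model identification uses blend (BLX-alpha) crossover
#' with Gaussian mutation; reduced-model identification switches to
#' simulated binary crossover (SBX, eta 15) with polynomial mutation
#' (eta 20) to keep diversity up when few genes are free. Iteration stops
#' early after `stall_generations` generations without an objective
#' improvement beyond `stall_tol`.
#'
#' @param population_size Number of chromosomes.
#' @param max_generations Generation cap (at most 1000).
#' @param crossover `"blend"` or `"sbx"`.
#' @param crossover_prob Per-pair crossover probability.
#' @param mutation `"gaussian"` or `"polynomial"`.
#' @param mutation_prob Per-gene mutation probability.
#' @param blend_alpha BLX-alpha exploration factor.
#' @param sbx_eta SBX distribution index.
#' @param mutation_eta Polynomial-mutation distribution index.
#' @param mutation_sd Gaussian mutation s.d. as a fraction of each bound
#'   range (initial value; annealed geometrically down to
#'   `mutation_sd / anneal_factor` by the final generation).
#' @param anneal_factor Total geometric decay of the Gaussian mutation scale
#'   over the run.
#' @param restarts Number of independent GA restarts; the generation budget
#'   is split evenly between them and the best chromosome overall is
#'   returned. Restarting guards against a single unlucky basin.
#' @param immigrants Number of random chromosomes injected into the
#'   population every generation (random-immigrants scheme), maintaining
#'   global exploration while the rest of the population exploits.
#' @param elitism_count Chromosomes copied unchanged each generation.
#' @param tournament_size Tournament size for selection.
#' @param stall_generations Early-stop patience.
#' @param stall_tol Minimum improvement counted as progress.
#' @param seed RNG seed (`NULL` = use current RNG state).
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 150, max_generations = 500,
                      crossover = c("blend", "sbx"), crossover_prob = 0.9,
                      mutation = c("gaussian", "polynomial"),
                      mutation_prob = 0.15, blend_alpha = 0.5, sbx_eta = 15,
                      mutation_eta = 20, mutation_sd = 0.1,
                      anneal_factor = 100, restarts = 1, immigrants = 0,
                      elitism_count = 2, tournament_size = 3,
                      stall_generations = 50, stall_tol = 1e-8, seed = NULL) {
  crossover <- match.arg(crossover)
  mutation <- match.arg(mutation)
  if (max_generations > 1000) {
    abort_config("max_generations is capped at 1000")
  }
  probs <- c(crossover_prob, mutation_prob)
  if (any(probs < 0 | probs > 1)) abort_config("probabilities must be in [0, 1]")
  structure(list(
    population_size = population_size, max_generations = max_generations,
    crossover = crossover, crossover_prob = crossover_prob,
    mutation = mutation, mutation_prob = mutation_prob,
    blend_alpha = blend_alpha, sbx_eta = sbx_eta,
    mutation_eta = mutation_eta, mutation_sd = mutation_sd,
    anneal_factor = anneal_factor, restarts = restarts,
    immigrants = immigrants,
    elitism_count = elitism_count, tournament_size = tournament_size,
    stall_generations = stall_generations, stall_tol = stall_tol,
    seed = seed), class = "ga_config")
}

# GA variation operators on matrices of free genes ----------------------------

ga_crossover <- function(P1, P2, cfg, lower, upper) {
  k <- ncol(P1); n <- nrow(P1)
  do_cx <- stats::runif(n) < cfg$crossover_prob
  C1 <- P1; C2 <- P2
  if (!any(do_cx)) return(list(C1, C2))
  i <- which(do_cx)
  if (cfg$crossover == "blend") {
    a <- cfg$blend_alpha
    lo <- pmin(P1[i, , drop = FALSE], P2[i, , drop = FALSE])
    hi <- pmax(P1[i, , drop = FALSE], P2[i, , drop = FALSE])
    d <- hi - lo
    U1 <- matrix(stats::runif(length(i) * k), length(i), k)
    U2 <- matrix(stats::runif(length(i) * k), length(i), k)
    C1[i, ] <- lo - a * d + U1 * (1 + 2 * a) * d
    C2[i, ] <- lo - a * d + U2 * (1 + 2 * a) * d
  } else {
    # simulated binary crossover, gene-wise
    u <- matrix(stats::runif(length(i) * k), length(i), k)
    eta <- cfg$sbx_eta
    beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                   (1 / (2 * (1 - u)))^(1 / (eta + 1)))
    x1 <- P1[i, , drop = FALSE]; x2 <- P2[i, , drop = FALSE]
    C1[i, ] <- 0.5 * ((1 + beta) * x1 + (1 - beta) * x2)
    C2[i, ] <- 0.5 * ((1 - beta) * x1 + (1 + beta) * x2)
  }
  list(C1, C2)
}

ga_mutate <- function(P, cfg, lower, upper, anneal = 1) {
  n <- nrow(P); k <- ncol(P)
  M <- matrix(stats::runif(n * k) < cfg$mutation_prob, n, k)
  if (!any(M)) return(P)
  rng <- matrix(upper - lower, n, k, byrow = TRUE)
  if (cfg$mutation == "gaussian") {
    P[M] <- P[M] + stats::rnorm(sum(M), 0, cfg$mutation_sd * anneal) * rng[M]
  } else {
    # polynomial mutation
    eta <- cfg$mutation_eta
    u <- stats::runif(sum(M))
    delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                    1 - (2 * (1 - u))^(1 / (eta + 1)))
    P[M] <- P[M] + delta * rng[M]
  }
  P
}

ga_clip <- function(P, lower, upper) {
  n <- nrow(P)
  LO <- matrix(lower, n, length(lower), byrow = TRUE)
  HI <- matrix(upper, n, length(upper), byrow = TRUE)
  pmin(pmax(P, LO), HI)
}

# Generic real-coded GA minimizer over a box. fn takes a pop x k matrix and
# returns one objective value per row. `init`, when given, joins the initial
# population (the subject-scaled physiological values are a natural first
# chromosome). With cfg$restarts > 1 the generation budget is split across
# independent runs and the best result wins; traces are concatenated.
ga_minimize <- function(fn, lower, upper, cfg, init = NULL) {
  restarts <- if (is.null(cfg$restarts)) 1L else as.integer(cfg$restarts)
  if (restarts > 1) {
    per <- cfg$max_generations %/% restarts
    best <- NULL
    trace <- numeric(0)
    gens <- 0L
    for (r in seq_len(restarts)) {
      cfg_r <- cfg
      cfg_r$restarts <- 1L
      cfg_r$max_generations <- per
      cfg_r$seed <- if (is.null(cfg$seed)) NULL else cfg$seed + 7919L * (r - 1L)
      res_r <- ga_minimize(fn, lower, upper, cfg_r, init = init)
      gens <- gens + res_r$generations
      # the reported trace stays nonincreasing across restarts
      trace <- c(trace, pmin(res_r$trace,
                             if (is.null(best)) Inf else best$f))
      if (is.null(best) || res_r$f < best$f) best <- res_r
    }
    return(list(x = best$x, f = best$f, trace = trace, generations = gens))
  }
  k <- length(lower)
  with_seed(cfg$seed, {
    pop <- cfg$population_size
    P <- matrix(stats::runif(pop * k), pop, k)
    P <- sweep(sweep(P, 2, upper - lower, "*"), 2, lower, "+")
    if (!is.null(init)) P[1, ] <- pmin(pmax(init, lower), upper)
    f <- fn(P)
    best_x <- P[which.min(f), ]; best_f <- min(f)
    trace <- numeric(cfg$max_generations)
    stall <- 0
    gen_done <- 0
    for (g in seq_len(cfg$max_generations)) {
      # tournament selection of parents
      pick <- function() {
        idx <- matrix(sample.int(pop, pop * cfg$tournament_size, replace = TRUE),
                      pop, cfg$tournament_size)
        sel <- idx[cbind(seq_len(pop), max.col(-matrix(f[idx], pop)))]
        sel
      }
      half <- pop %/% 2
      p1 <- pick()[seq_len(half)]; p2 <- pick()[seq_len(half)]
      ch <- ga_crossover(P[p1, , drop = FALSE], P[p2, , drop = FALSE], cfg,
                         lower, upper)
      Q <- rbind(ch[[1]], ch[[2]])
      if (nrow(Q) < pop) Q <- rbind(Q, P[sample.int(pop, pop - nrow(Q)), ,
                                         drop = FALSE])
      # geometric annealing of the Gaussian mutation scale (x1 down to
      # x1/anneal_factor over the run) sharpens late-stage exploitation
      # without losing early search
      Q <- ga_mutate(Q, cfg, lower, upper,
                     anneal = cfg$anneal_factor^(-(g - 1) /
                                                   max(cfg$max_generations - 1, 1)))
      Q <- ga_clip(Q, lower, upper)
      imm <- if (is.null(cfg$immigrants)) 0L else cfg$immigrants
      if (imm > 0) {
        # random immigrants keep global exploration alive late in the run
        fresh <- matrix(stats::runif(imm * k), imm, k)
        fresh <- sweep(sweep(fresh, 2, upper - lower, "*"), 2, lower, "+")
        Q[cfg$elitism_count + seq_len(imm), ] <- fresh
      }
      # elitism: carry the best chromosomes over unchanged
      if (cfg$elitism_count > 0) {
        elite <- order(f)[seq_len(min(cfg$elitism_count, pop))]
        Q[seq_along(elite), ] <- P[elite, , drop = FALSE]
      }
      P <- Q
      f <- fn(P)
      improved <- min(f) < best_f - cfg$stall_tol
      if (min(f) < best_f) {
        best_f <- min(f); best_x <- P[which.min(f), ]
      }
      trace[g] <- best_f
      gen_done <- g
      stall <- if (improved) 0 else stall + 1
      if (stall >= cfg$stall_generations) break
    }
    list(x = best_x, f = best_f, trace = trace[seq_len(gen_done)],
         generations = gen_done)
  })
}

#' Identify model parameters with a real-coded genetic algorithm
#'
#' Minimizes [torque_objective()] over the bounded 26-parameter box.
#' Chromosomes are floating-point vectors of the free parameters; fixed
#' parameters are held at `fixed_values`. Deterministic given
#' `config$seed`; bounds are enforced at every generation.
#'
#' @param data Aligned dataset with reference torque.
#' @param bounds A [make_bounds()] object.
#' @param config A [ga_config()].
#' @param free_mask Logical 26-vector (canonical order): which parameters are
#'   identified. Default: all.
#' @param fixed_values A [param_vector()] supplying the entries where
#'   `free_mask` is `FALSE` (required if any).
#' @param kpe Passive shape constant.
#' @return An object of class `emg_fit`: `lambda_opt`, `objective_trace`
#'   (best-so-far MSE per generation, nonincreasing), `metrics` (rmse,
#'   nrmse_pct, r2 on the identification data), `free_mask`, `seed`,
#'   `config`.
#' @export
ga_identify <- function(data, bounds = make_bounds(), config = ga_config(),
                        free_mask = rep(TRUE, 26), fixed_values = NULL,
                        kpe = 5) {
  prep <- if (inherits(data, "emgknee_prep")) data else prepare_dataset(data)
  if (is.null(prep$tau_ref)) abort_schema("dataset has no tau_ref column")
  free_mask <- as.logical(free_mask)
  if (length(free_mask) != 26 || !any(free_mask)) {
    abort_config("free_mask must be a logical 26-vector with at least one TRUE")
  }
  if (any(!free_mask) && is.null(fixed_values)) {
    abort_config("fixed_values is required when some parameters are fixed")
  }
  base <- if (is.null(fixed_values)) {
    0.5 * (bounds$lower + bounds$upper)
  } else {
    unclass(param_vector(fixed_values))
  }
  expand <- function(G) {
    # G: pop x n_free -> pop x 26
    L <- matrix(base, nrow(G), 26, byrow = TRUE)
    L[, free_mask] <- G
    L
  }
  fn <- function(G) objective_batch(prep, expand(G), kpe)
  res <- ga_minimize(fn, bounds$lower[free_mask], bounds$upper[free_mask],
                     config, init = base[free_mask])
  lambda <- param_vector(expand(matrix(res$x, nrow = 1))[1, ])
  metrics <- evaluate_fit(lambda, prep, kpe = kpe)
  structure(list(
    lambda_opt = lambda,
    objective_trace = res$trace,
    generations = res$generations,
    metrics = metrics,
    free_mask = free_mask,
    seed = config$seed,
    config = config,
    bounds = bounds
  ), class = "emg_fit")
}

#' Torque-tracking metrics of a parameter vector
#'
#' RMSE in N m, NRMSE as a percentage of the reference torque range
#' (`100 * rmse / (max(tau_ref) - min(tau_ref))`), and the coefficient of
#' determination `r2 = 1 - SS_res / SS_tot` about the reference mean.
#'
#' @param lambda A [param_vector()].
#' @param data Aligned dataset with `tau_ref` (identification or validation).
#' @param kpe Passive shape constant.
#' @return A list with `rmse`, `nrmse_pct`, `r2`.
#' @export
evaluate_fit <- function(lambda, data, kpe = 5) {
  prep <- if (inherits(data, "emgknee_prep")) data else prepare_dataset(data)
  if (is.null(prep$tau_ref)) abort_schema("dataset has no tau_ref column")
  ref <- prep$tau_ref
  rng <- max(ref) - min(ref)
  ss_tot <- sum((ref - mean(ref))^2)
  if (rng <= 0 || ss_tot <= 0) {
    abort_numeric("reference torque is constant; NRMSE and R2 are undefined")
  }
  tau <- forward_torque(prep, lambda, kpe)$tau
  rmse <- sqrt(mean((tau - ref)^2))
  list(rmse = rmse,
       nrmse_pct = 100 * rmse / rng,
       r2 = 1 - sum((tau - ref)^2) / ss_tot)
}

#' @export
print.emg_fit <- function(x, ...) {
  cat("<emg_fit>\n")
  cat(sprintf("  free parameters: %d of 26\n", sum(x$free_mask)))
  cat(sprintf("  generations:     %d\n", x$generations))
  cat(sprintf("  best MSE:        %.6g (N m)^2\n", min(x$objective_trace)))
  cat(sprintf("  RMSE %.4g N m | NRMSE %.3g%% | R2 %.4g\n",
              x$metrics$rmse, x$metrics$nrmse_pct, x$metrics$r2))
  invisible(x)
}

#' Tidy and glance methods for fitted models
#'
#' `tidy()` returns one row per parameter with its estimate, bounds and
#' whether it was free during identification; `glance()` returns a one-row
#' summary of fit quality.
#'
#' @param x An `emg_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.emg_fit <- function(x, ...) {
  out <- tidy(x$lambda_opt)
  out$estimate <- out$value
  out$value <- NULL
  out$lower <- as.numeric(x$bounds$lower)
  out$upper <- as.numeric(x$bounds$upper)
  out$free <- x$free_mask
  out
}

#' @rdname tidy.emg_fit
#' @export
glance.emg_fit <- function(x, ...) {
  tibble::tibble(rmse = x$metrics$rmse, nrmse_pct = x$metrics$nrmse_pct,
                 r2 = x$metrics$r2, n_free = sum(x$free_mask),
                 generations = x$generations,
                 best_mse = min(x$objective_trace))
}
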