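#' Sensitivity-based model simplification
#'
#' Parameters whose total-effect sensitivity is low can be frozen at
#' population means without materially degrading an individual's torque
#' model. The procedure: (1) average the sensitivity indices across
#' subjects; (2) collect parameters implicated in strong pairwise
#' interactions - these are mandatory in every reduced model; (3) form the
#' simplest model from the mandatory set; (4) grow the identified set in
#' descending mean-sensitivity order, re-identifying at each size `q` and
#' recording the precision ratio `R = RMSE_original / RMSE_simplified`;
#' (5) pick the `q` that fits the application's accuracy/cost trade-off
#' (reported as a curve, not chosen automatically).
#'
#' @name model_simplification
NULL

#' Rank parameters and build a simplification plan
#'
#' @param sens_results List of `emg_sobol` results, one per subject.
#' @param fits List of `emg_fit` (or `param_vector`) of the same subjects;
#'   their elementwise mean provides the fixed values of frozen parameters.
#' @param s1_threshold Mean-S1 threshold above which a parameter is flagged
#'   high-sensitivity (reporting aid; ranking itself uses mean ST).
#' @param s2_threshold A screened pair with `S2` above this marks both
#'   members mandatory.
#' @param rank_by `"ST"` (default, the primary criterion) or `"S1"`.
#' @return An object of class `simplification_plan`: `ranking` (26 indices,
#'   descending mean sensitivity, ties by index), `mandatory`,
#'   `high_sensitivity`, `fixed_values` (mean [param_vector()]), `mean_S1`,
#'   `mean_ST`.
#' @export
rank_parameters <- function(sens_results, fits, s1_threshold = 0.05,
                            s2_threshold = 0.05, rank_by = c("ST", "S1")) {
  rank_by <- match.arg(rank_by)
  if (length(sens_results) == 0) abort_invalid("need at least one sensitivity result")
  S1 <- rowMeans(vapply(sens_results, function(s) s$S1, numeric(26)))
  ST <- rowMeans(vapply(sens_results, function(s) s$ST, numeric(26)))
  lam <- vapply(fits, function(f) {
    as.numeric(unclass(if (inherits(f, "emg_fit")) f$lambda_opt else param_vector(f)))
  }, numeric(26))
  fixed_values <- param_vector(rowMeans(lam))
  key <- if (rank_by == "ST") ST else S1
  ranking <- order(-key, seq_len(26))          # ties broken by index
  mandatory <- sort(unique(unlist(lapply(sens_results, function(s) {
    if (nrow(s$S2) == 0) return(integer(0))
    keep <- s$S2$S2 > s2_threshold
    c(s$S2$i[keep], s$S2$j[keep])
  }))))
  structure(list(
    ranking = ranking,
    mandatory = mandatory,
    high_sensitivity = which(S1 > s1_threshold),
    fixed_values = fixed_values,
    mean_S1 = S1, mean_ST = ST, rank_by = rank_by
  ), class = "simplification_plan")
}

#' @export
print.simplification_plan <- function(x, ...) {
  cat("<simplification_plan>\n")
  cat("  ranking head:", paste(param_names()[x$ranking[1:8]], collapse = ", "),
      "...\n")
  cat("  mandatory:   ",
      if (length(x$mandatory)) paste(param_names()[x$mandatory], collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Tidy a simplification plan
#'
#' @param x A `simplification_plan`.
#' @param ... Unused.
#' @return Tibble with per-parameter mean indices, rank and flags.
#' @export
tidy.simplification_plan <- function(x, ...) {
  tibble::tibble(
    index = 1:26, term = param_names(),
    mean_S1 = x$mean_S1, mean_ST = x$mean_ST,
    rank = match(1:26, x$ranking),
    mandatory = 1:26 %in% x$mandatory,
    high_sensitivity = 1:26 %in% x$high_sensitivity)
}

#' Free parameter set of a reduced model of size q
#'
#' The mandatory (high-interaction) parameters are always included; the rest
#' of the set is filled with the top-ranked parameters until `q` are free.
#' Sets are nested in `q` by construction.
#'
#' @param plan A [rank_parameters()] plan.
#' @param q Number of identified parameters, `length(plan$mandatory) <= q <=
#'   26`.
#' @return Sorted integer vector of free parameter indices.
#' @export
free_set <- function(plan, q) {
  if (q < length(plan$mandatory) || q > 26) {
    abort_config(sprintf("q must be between %d (mandatory set) and 26",
                         length(plan$mandatory)))
  }
  free <- plan$mandatory
  for (i in plan$ranking) {
    if (length(free) >= q) break
    if (!(i %in% free)) free <- c(free, i)
  }
  sort(free)
}

#' Identify a reduced model
#'
#' Runs the GA with only the `q` free parameters of [free_set()]
#' identifiable; all others are frozen at the plan's cross-subject means.
#' Reduced runs default to SBX crossover and polynomial mutation, which keep
#' variation effective on short chromosomes.
#'
#' @param data Aligned dataset of one subject.
#' @param plan A [rank_parameters()] plan.
#' @param q Number of identified parameters.
#' @param bounds A [make_bounds()] object.
#' @param config A [ga_config()]; crossover/mutation default to
#'   `"sbx"`/`"polynomial"` here.
#' @param kpe Passive shape constant.
#' @return An `emg_fit`.
#' @export
reduced_identify <- function(data, plan, q, bounds = make_bounds(),
                             config = ga_config(crossover = "sbx",
                                                mutation = "polynomial"),
                             kpe = 5) {
  free <- free_set(plan, q)
  mask <- seq_len(26) %in% free
  ga_identify(data, bounds, config, free_mask = mask,
              fixed_values = plan$fixed_values, kpe = kpe)
}

#' Precision ratio of a simplified model
#'
#' `R = RMSE_original / RMSE_simplified`: the simplified model attains
#' `R * 100%` of the original model's accuracy (R near 1 means no loss;
#' R can exceed 1 when the reduced search space helps the optimizer).
#'
#' @param rmse_original,rmse_simplified RMSEs of the full and reduced fits,
#'   N m (positive).
#' @return The ratio `R`; `Inf` with a warning when `rmse_simplified` is 0.
#' @export
precision_ratio <- function(rmse_original, rmse_simplified) {
  if (rmse_original < 0 || rmse_simplified < 0) {
    abort_invalid("RMSEs must be nonnegative")
  }
  if (rmse_simplified == 0) {
    rlang::warn("simplified-model RMSE is zero; precision ratio is infinite",
                class = "emgknee_undefined_ratio")
    return(Inf)
  }
  rmse_original / rmse_simplified
}

#' Sweep the number of identified parameters
#'
#' For each subject and each `q` in `q_grid`, identifies the reduced model
#' and records its metrics and precision ratio against the subject's full
#' fit. Every `q` gets the same GA budget so ratios compare like with like.
#'
#' @param datasets Named list of per-subject aligned datasets.
#' @param plan A [rank_parameters()] plan.
#' @param full_fits Named list of full-model `emg_fit`s (same names).
#' @param q_grid Integer vector of model sizes.
#' @param bounds A [make_bounds()] object.
#' @param config A [ga_config()] for the reduced runs.
#' @param seed Base seed; each (subject, q) run gets a split seed, so the
#'   report regenerates exactly.
#' @param kpe Passive shape constant.
#' @return An object of class `simplification_report`: tibble `results` with
#'   one row per (subject, q) - `rmse`, `nrmse_pct`, `r2`, `R`,
#'   `reduction_pct` - plus the `plan` and `q_grid`.
#' @export
q_sweep <- function(datasets, plan, full_fits, q_grid = c(4, 10, 16, 26),
                    bounds = make_bounds(),
                    config = ga_config(crossover = "sbx",
                                       mutation = "polynomial"),
                    seed = 1, kpe = 5) {
  subjects <- names(datasets)
  if (is.null(subjects)) subjects <- paste0("S", seq_along(datasets))
  rows <- list()
  fits <- list()
  for (s in seq_along(datasets)) {
    prep <- prepare_dataset(datasets[[s]])
    rmse_full <- if (inherits(full_fits[[s]], "emg_fit")) {
      full_fits[[s]]$metrics$rmse
    } else {
      evaluate_fit(full_fits[[s]], prep, kpe = kpe)$rmse
    }
    for (q in q_grid) {
      cfg_q <- config
      cfg_q$seed <- split_seed(seed, paste0(subjects[s], "_q", q))
      fit <- reduced_identify(prep, plan, q, bounds, cfg_q, kpe = kpe)
      fits[[paste0(subjects[s], "_q", q)]] <- fit
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = subjects[s], q = q,
        rmse = fit$metrics$rmse, nrmse_pct = fit$metrics$nrmse_pct,
        r2 = fit$metrics$r2,
        R = precision_ratio(rmse_full, fit$metrics$rmse),
        reduction_pct = 100 * (26 - q) / 26)
    }
  }
  structure(list(results = dplyr::bind_rows(rows), plan = plan,
                 q_grid = q_grid, seed = seed, fits = fits),
            class = "simplification_report")
}

#' @export
print.simplification_report <- function(x, ...) {
  cat("<simplification_report>\n")
  print(x$results, n = 20)
  invisible(x)
}

#' Tidiers for simplification reports
#'
#' @param x A `simplification_report`.
#' @param ... Unused.
#' @return `tidy()`: the per-(subject, q) results tibble. `glance()`: one
#'   row per q with the median precision ratio across subjects.
#' @export
tidy.simplification_report <- function(x, ...) {
  x$results
}

#' @rdname tidy.simplification_report
#' @export
glance.simplification_report <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$results, .data$q),
                   median_R = stats::median(.data$R),
                   median_nrmse_pct = stats::median(.data$nrmse_pct),
                   reduction_pct = .data$reduction_pct[1],
                   .groups = "drop")
}
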