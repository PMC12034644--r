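#' Plot a fitted model's torque against the reference
#'
#' @param fit An `emg_fit`.
#' @param data Aligned dataset (identification or validation trial).
#' @param kpe Passive shape constant.
#' @return A ggplot: reference and model torque vs time.
#' @export
plot_torque_fit <- function(fit, data, kpe = 5) {
  data <- tibble::as_tibble(data)
  est <- forward_torque(data, fit$lambda_opt, kpe)
  d <- dplyr::bind_rows(
    tibble::tibble(time_s = data$time_s, tau = data$tau_ref,
                   series = "reference"),
    tibble::tibble(time_s = est$time_s, tau = est$tau, series = "model"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$tau,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "knee torque (N m)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.emg_fit <- function(object, ...) {
  d <- tibble::tibble(generation = seq_along(object$objective_trace),
                      mse = object$objective_trace)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$generation, y = .data$mse)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "best MSE (N m)^2",
                  title = "GA convergence") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.emg_sobol <- function(object, ...) {
  d <- tidyr::pivot_longer(tidy(object)[c("term", "S1", "ST")], c("S1", "ST"),
                           names_to = "order", values_to = "index")
  d$term <- factor(d$term, levels = object$terms)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$index,
                                  fill = .data$order)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "sensitivity index", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @export
autoplot.simplification_report <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$q, y = .data$R,
                               colour = .data$subject)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "identified parameters q", y = "precision ratio R",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
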