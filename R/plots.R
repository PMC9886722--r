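#' Plot survival curves
#'
#' One line per condition with mean +/- SD error bars over age days,
#' mirroring the standard chronological-lifespan survival graph.
#'
#' @param curves A `survival_curves` tibble from [build_survival_curve()].
#' @return A ggplot object.
#' @export
plot_survival_curves <- function(curves) {
  d <- as_tibble(curves) %>%
    mutate(condition = paste0(
      .data$compound,
      dplyr::if_else(is.na(.data$concentration), "",
                     paste0(" ", .data$concentration))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age_day, y = .data$survival_pct,
                                  colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$survival_pct - .data$sd_pct),
                   ymax = pmin(100, .data$survival_pct + .data$sd_pct)),
      width = 0.3) +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "Age (days)", y = "Survival (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_survival_curves
#' @param object,... Passed through for the `autoplot` method.
#' @export
autoplot.survival_curves <- function(object, ...) {
  plot_survival_curves(object)
}

#' Plot a calibration fit
#'
#' Retained points with the fitted line; points excluded by linear-range
#' trimming shown as open triangles.
#'
#' @param object A `calibration_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_fit <- function(object, ...) {
  d <- object$data
  names(d) <- c("x", "y")[seq_len(2)]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "cuvette OD600", y = "response",
      subtitle = sprintf("slope %.3g, R^2 %.4f, linear range [%.3g, %.3g]",
                         object$slope, object$r_squared,
                         object$range_lo, object$range_hi)) +
    ggplot2::theme_minimal()
  if (nrow(object$excluded_points) > 0) {
    ex <- object$excluded_points
    names(ex)[1:2] <- c("x", "y")
    p <- p + ggplot2::geom_point(data = ex, shape = 2, colour = "firebrick")
  }
  p
}

#' Plot a dose-response summary
#'
#' Curve AUC against concentration, one panel per compound.
#'
#' @param dr A `dose_response_table` from [summarize_dose_response()].
#' @return A ggplot object.
#' @export
plot_dose_response <- function(dr) {
  ggplot2::ggplot(as_tibble(dr),
                  ggplot2::aes(x = .data$concentration, y = .data$auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$compound), scales = "free_x") +
    ggplot2::labs(x = "Concentration", y = "Survival AUC (%·days)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
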