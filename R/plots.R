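# ggplot2 views of curves and fits.

fit_curve_frame <- function(fit, n = 200L) {
  t <- fit$data$time_min
  grid <- seq(min(t), max(t), length.out = n)
  tibble(
    time_min = grid,
    Q_percent = evaluate_model(fit$model, fit$params, grid),
    model = fit$model
  )
}

#' Plot a fitted release model
#'
#' Observed points with the fitted curve overlaid.
#'
#' @param object A `release_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.release_fit <- function(object, ...) {
  ggplot2::ggplot(augment(object), ggplot2::aes(.data$time_min, .data$Q_percent)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = fit_curve_frame(object),
      ggplot2::aes(.data$time_min, .data$Q_percent),
      colour = "steelblue"
    ) +
    ggplot2::labs(
      x = "time (min)", y = "cumulative release (%)",
      title = object$equation, subtitle = object$model
    )
}

#' Plot all fitted models for one curve
#'
#' @param object A `release_fit_set`.
#' @param ... Unused.
#' @return A ggplot object faceted by model.
#' @exportS3Method ggplot2::autoplot
autoplot.release_fit_set <- function(object, ...) {
  pts <- purrr::map_dfr(unclass(object), function(f) {
    dplyr::mutate(augment(f), model = f$model)
  })
  lines <- purrr::map_dfr(unclass(object), fit_curve_frame)
  ggplot2::ggplot(pts, ggplot2::aes(.data$time_min, .data$Q_percent)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = lines, colour = "steelblue") +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "time (min)", y = "cumulative release (%)")
}

#' Plot release curves
#'
#' @param curves Long data frame with columns `drug`, `time_min`,
#'   `Q_percent` (or a single curve without `drug`).
#' @return A ggplot object.
#' @export
plot_release_curves <- function(curves) {
  curves <- as_tibble(curves)
  p <- ggplot2::ggplot(curves, ggplot2::aes(.data$time_min, .data$Q_percent))
  if ("drug" %in% names(curves)) {
    p <- p + ggplot2::aes(colour = .data$drug)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (min)", y = "cumulative release (%)")
}
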