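#' Plot methods
#'
#' `autoplot()` methods for the package's result types, in the usual
#' ggplot2 idiom: trajectories as state-versus-time (or versus the driven
#' parameter when one is recorded), recovery experiments as mean curves
#' with ribbons, estimates as the maxima-versus-parameter extrapolation
#' picture, and EWS traces as facetted indicator panels.
#'
#' @param object the object to plot.
#' @param against `"time"` or `"parameter"` for trajectories.
#' @param ... unused.
#'
#' @return A ggplot object.
#' @name autoplot-methods
NULL

#' @rdname autoplot-methods
#' @export
autoplot.ising_trajectory <- function(object, against = c("time", "parameter"), ...) {
  against <- match.arg(against)
  ggplot2::ggplot(object, ggplot2::aes(.data[[against]], .data$state)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = if (against == "time") "time" else attr(object, "parameter_name"),
      y = "magnetization"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @export
autoplot.hysteresis_loop <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$parameter, .data$state,
    colour = .data$direction
  )) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "external field H", y = "magnetization") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @export
autoplot.recovery_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$step, .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = attr(object, "y_eq"), linetype = 2) +
    ggplot2::labs(
      x = "steps after perturbation", y = "magnetization",
      title = sprintf("%s = %g", attr(object, "parameter"), attr(object, "value"))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @export
autoplot.recovery_experiment <- function(object, ...) {
  dat <- dplyr::bind_rows(purrr::map(object, function(cv) {
    tibble::tibble(
      value = attr(cv, "value"), step = cv$step,
      mean = cv$mean, sd = cv$sd
    )
  }))
  spec <- attr(object, "spec")
  ggplot2::ggplot(dat, ggplot2::aes(.data$step, .data$mean,
    colour = factor(.data$value)
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "steps after perturbation", y = "magnetization",
      colour = spec$parameter
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @export
autoplot.bifurcation_estimate <- function(object, ...) {
  dat <- object$data
  ggplot2::ggplot(dat, ggplot2::aes(.data$c, .data$m)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept,
      linetype = 2, colour = "red"
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "blue") +
    ggplot2::geom_vline(xintercept = object$c_hat, linetype = 3) +
    ggplot2::labs(
      x = "perturbation parameter",
      y = "maximal fitted recovery rate",
      title = sprintf("estimated bifurcation at %.4g", object$c_hat)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @export
autoplot.ews_trace <- function(object, ...) {
  xvar <- if (all(is.na(object$parameter))) "end" else "parameter"
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("ar1", "std", "skewness", "kurtosis", "dfa", "fr"),
    names_to = "indicator", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data[[xvar]], .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~indicator, scales = "free_y") +
    ggplot2::labs(x = xvar, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @export
autoplot.sweep_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$parameter, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = if (attr(object, "scenario") == "saddle") "external field H" else "temperature T",
      y = "magnetization"
    ) +
    ggplot2::theme_minimal()
}
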