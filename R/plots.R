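#' Plot uptake curves on a log-time axis
#'
#' @param data Tibble with `exposure`, `uptake` and (optionally) a grouping
#'   column named by `colour`.
#' @param colour Optional name of a column to colour by (e.g. `"sequence"`).
#' @return A ggplot.
#' @export
plot_uptake_curves <- function(data, colour = NULL) {
  stopifnot(is.data.frame(data))
  p <- ggplot2::ggplot(
    data,
    if (is.null(colour)) {
      ggplot2::aes(x = .data$exposure, y = .data$uptake)
    } else {
      ggplot2::aes(
        x = .data$exposure, y = .data$uptake,
        colour = .data[[colour]]
      )
    }
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "labeling time (s)", y = "deuterium uptake (Da)",
      colour = colour
    ) +
    ggplot2::theme_minimal()
  p
}

#' @export
autoplot.hdx_fit <- function(object, intrinsic = NULL, ...) {
  times <- 10^seq(
    log10(min(object$data$exposure)), log10(max(object$data$exposure)),
    length.out = 200
  )
  curve <- tibble::tibble(exposure = times, uptake = predict(object, times))
  p <- ggplot2::ggplot(
    object$data, ggplot2::aes(x = .data$exposure, y = .data$uptake)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = curve, colour = "firebrick", linetype = "dashed"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "labeling time (s)", y = "absolute uptake (Da)",
      title = sprintf(
        "%d-phase stretched-exponential fit (R² = %.3f)",
        object$n_phases, object$r_squared
      )
    ) +
    ggplot2::theme_minimal()
  if (!is.null(intrinsic)) {
    icurve <- tibble::tibble(
      exposure = times, uptake = predict(intrinsic, times)
    )
    p <- p + ggplot2::geom_line(
      data = icurve, colour = "black", linetype = "dotted"
    )
  }
  p
}

#' @export
autoplot.decay_fit <- function(object, data = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = data, ggplot2::aes(x = .data$time, y = .data$signal)
    )
    tmax <- max(data$time)
  } else {
    tmax <- 5 / max(object$k, 1e-6)
  }
  times <- seq(0, tmax, length.out = 200)
  curve <- tibble::tibble(
    time = times,
    signal = object$a0 * exp(-object$k * times) + object$c0
  )
  p + ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$time, y = .data$signal),
    colour = "steelblue"
  ) +
    ggplot2::labs(
      x = "time (s)", y = "signal",
      title = sprintf(
        "first-order decay: k = %.3g /s (95%% CI %.3g-%.3g)",
        object$k, object$conf_low, object$conf_high
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bex_model <- function(object, ...) {
  ggplot2::ggplot(
    object$per_exposure,
    ggplot2::aes(x = .data$exposure, y = .data$retention)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::geom_hline(
      yintercept = object$retention, linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "mixing time (s)", y = "retention fraction",
      title = sprintf(
        "back-exchange retention %.3f (slope %.2g /s, R² %.2f)",
        object$retention, object$slope, object$r_squared
      )
    ) +
    ggplot2::theme_minimal()
}
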