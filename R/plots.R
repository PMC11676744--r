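#' Plot survival-yield breakdown curves
#'
#' One line per sample over the excitation-voltage ladder, coloured by the
#' linear-peptide molar ratio when available: mixture curves fall between
#' the pure cyclic (high-voltage) and pure linear (low-voltage) sigmoids.
#'
#' @param curves SY-curve tibble from [build_sy_curves()].
#' @param highlight_voltage Optional voltage to mark (e.g. the univariate
#'   calibration voltage).
#' @return A ggplot.
#' @export
plot_sy_curves <- function(curves, highlight_voltage = NULL) {
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(.data$voltage_V, .data$sy,
                                    group = .data$sample_id))
  p <- if ("ratio" %in% names(curves)) {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$ratio)) +
      ggplot2::scale_colour_viridis_c(name = "linear molar ratio")
  } else {
    p + ggplot2::geom_line()
  }
  if (!is.null(highlight_voltage)) {
    p <- p + ggplot2::geom_vline(xintercept = highlight_voltage,
                                 linetype = "dashed", colour = "orange")
  }
  p + ggplot2::labs(x = "excitation voltage (V)", y = "survival yield") +
    ggplot2::theme_minimal()
}

#' Plot IR spectra
#'
#' @param spectra Long IR tibble.
#' @param value_col Intensity column to draw (`"absorbance"`, or
#'   `"corrected"` after [asls_correct()]).
#' @param band_window Optional wavenumber window to shade (default the
#'   linear-peptide alkyne/azide band).
#' @return A ggplot.
#' @export
plot_ir_spectra <- function(spectra, value_col = "absorbance",
                            band_window = c(2040, 2170)) {
  p <- ggplot2::ggplot(spectra,
                       ggplot2::aes(.data$wavenumber_cm1,
                                    .data[[value_col]],
                                    group = .data$sample_id))
  if (!is.null(band_window)) {
    p <- p + ggplot2::annotate("rect", xmin = band_window[1],
                               xmax = band_window[2], ymin = -Inf, ymax = Inf,
                               alpha = 0.12, fill = "steelblue")
  }
  p <- if ("ratio" %in% names(spectra)) {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$ratio), linewidth = 0.3) +
      ggplot2::scale_colour_viridis_c(name = "linear molar ratio")
  } else {
    p + ggplot2::geom_line(linewidth = 0.3)
  }
  p + ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(wavenumber ~ (cm^-1)), y = value_col) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.boltzmann_fit <- function(object, ...) {
  grid <- tibble::tibble(voltage_V = seq(min(object$data$voltage_V),
                                         max(object$data$voltage_V),
                                         length.out = 200))
  grid$sy <- boltzmann_sy(grid$voltage_V, object$params)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$voltage_V, .data$sy)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "excitation voltage (V)", y = "survival yield",
                  subtitle = sprintf("V0 = %.3f V, dV = %.3f V",
                                     object$params$V0, object$params$dV)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.univariate_cal <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$ratio, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$b0, slope = object$b1,
                         colour = "firebrick") +
    ggplot2::labs(x = "linear molar ratio", y = "response",
                  subtitle = sprintf("slope %.4g, R2 = %.4f", object$b1,
                                     object$r2)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.segmented_cal <- function(object, ...) {
  bp <- object$breakpoint
  seg_line <- function(m, from, to) {
    tibble::tibble(ratio = c(from, to),
                   response = m$b0 + m$b1 * c(from, to))
  }
  lows <- seg_line(object$low_model, min(object$low_model$data$ratio), bp)
  highs <- seg_line(object$high_model, bp, max(object$high_model$data$ratio))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$ratio, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = lows, colour = "red") +
    ggplot2::geom_line(data = highs, colour = "blue") +
    ggplot2::geom_vline(xintercept = bp, linetype = "dotted") +
    ggplot2::labs(x = "linear molar ratio", y = "response") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.quadratic_cal <- function(object, ...) {
  grid <- tibble::tibble(ratio = seq(min(object$data$ratio),
                                     max(object$data$ratio), length.out = 200))
  grid$response <- object$c0 + object$c1 * grid$ratio + object$c2 * grid$ratio^2
  ggplot2::ggplot(object$data, ggplot2::aes(.data$ratio, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "linear molar ratio", y = "response") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pls_cal <- function(object, ...) {
  d <- tibble::tibble(reference = object$y, predicted = object$fitted,
                      cv = object$cv_pred)
  ggplot2::ggplot(d, ggplot2::aes(.data$reference, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "darkgreen") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "reference molar ratio", y = "predicted molar ratio",
                  subtitle = sprintf("%d LVs, RMSEC %.3g, RMSECV %.3g",
                                     object$n_lv, object$rmsec,
                                     object$rmsecv)) +
    ggplot2::theme_minimal()
}
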