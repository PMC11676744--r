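#' Univariate delta-SY response at a fixed voltage
#'
#' The single-voltage calibration response: the drop of a mixture's
#' survival yield below the pure cyclic peptide's at one excitation
#' voltage, `SY_cyc(v) - SY_mix(v)`. Any admixture of the (more fragile)
#' linear isomer lowers the mixture SY, so the response grows with the
#' linear molar ratio.
#'
#' @param curve_mix,curve_cyclic SY-curve data frames (`voltage_V`, `sy`).
#' @param v Excitation voltage, typically the most discriminating one
#'   (2.2 V for the default curves).
#' @param mode,tol Passed to [sy_at_voltage()].
#' @return The scalar response.
#' @export
delta_sy_response <- function(curve_mix, curve_cyclic, v,
                              mode = "measured", tol = 1e-9) {
  sy_at_voltage(curve_cyclic, v, mode, tol = tol) -
    sy_at_voltage(curve_mix, v, mode, tol = tol)
}

#' Classical least squares unmixing of a survival-yield curve
#'
#' Expresses a mixture's SY curve as the least-squares convex-style
#' combination of the pure-component curves,
#' `SY_mix = a SY_lin + (1 - a) SY_cyc + e`, over a common voltage grid.
#' With one free coefficient the minimiser has the closed form
#' `a = <m - c, l - c> / <l - c, l - c>`. The coefficient is deliberately
#' not clipped to \[0, 1\]: out-of-range values are diagnostic of noise or
#' reference failure and must survive to reporting.
#'
#' @param curve_mix,curve_lin,curve_cyc SY-curve data frames on the same
#'   voltage grid (`voltage_V`, `sy`).
#' @param grid_tol Tolerance for the common-grid check (V).
#' @return A `cls_fit` object: `a`, `residuals` (tibble `voltage_V`,
#'   `residual`), `rss`.
#' @examples
#' g <- seq(1.7, 2.9, 0.1)
#' l <- tibble::tibble(voltage_V = g, sy = boltzmann_sy(g, boltzmann_params(V0 = 2.1, dV = 0.1)))
#' c <- tibble::tibble(voltage_V = g, sy = boltzmann_sy(g, boltzmann_params(V0 = 2.6, dV = 0.1)))
#' m <- tibble::tibble(voltage_V = g, sy = 0.3 * l$sy + 0.7 * c$sy)
#' cls_coefficient(m, l, c)$a
#' @export
cls_coefficient <- function(curve_mix, curve_lin, curve_cyc, grid_tol = 1e-9) {
  grids <- list(curve_mix$voltage_V, curve_lin$voltage_V, curve_cyc$voltage_V)
  if (length(unique(lengths(grids))) != 1 ||
      max(abs(grids[[1]] - grids[[2]]), abs(grids[[1]] - grids[[3]])) > grid_tol) {
    cp_abort("All three curves must share one voltage grid.", "grid_mismatch")
  }
  m <- curve_mix$sy; l <- curve_lin$sy; cc <- curve_cyc$sy
  d <- l - cc
  denom <- sum(d^2)
  if (denom <= 0) {
    cp_abort("Pure-component curves are identical: components indistinguishable.",
             "indistinguishable")
  }
  a <- sum((m - cc) * d) / denom
  e <- m - a * l - (1 - a) * cc
  structure(list(a = a,
                 residuals = tibble::tibble(voltage_V = curve_mix$voltage_V,
                                            residual = e),
                 rss = sum(e^2)),
            class = "cls_fit")
}

#' @export
print.cls_fit <- function(x, ...) {
  cat(sprintf("CLS unmixing: a = %.5f (rss = %.3g over %d voltages)\n",
              x$a, x$rss, nrow(x$residuals)))
  invisible(x)
}

check_standards <- function(standards, min_distinct, what) {
  if (!all(c("ratio", "response") %in% names(standards))) {
    cp_abort("`standards` needs `ratio` and `response` columns.", "format")
  }
  if (any(standards$ratio < 0 | standards$ratio > 1)) {
    cp_abort("Standard ratios must lie in [0, 1].", "config")
  }
  if (dplyr::n_distinct(standards$ratio) < min_distinct) {
    cp_abort(sprintf("%s needs >= %d distinct ratios.", what, min_distinct),
             "rank_deficiency")
  }
  invisible(standards)
}

#' Fit a straight-line calibration
#'
#' Ordinary least squares of a scalar response (delta-SY, CLS coefficient,
#' or IR band area) on the linear-peptide molar ratio. The residual
#' standard deviation `se` uses n - 2 degrees of freedom.
#'
#' @param standards Tibble of calibration standards with columns `ratio`,
#'   `response` and optionally `replicate`.
#' @return A `univariate_cal` object with `b0`, `b1`, `se`, `r2`, `n`, the
#'   underlying [lm] fit and the data. Supports [predict_ratio()],
#'   [generics::tidy()], [generics::glance()], [ggplot2::autoplot()].
#' @examples
#' std <- tibble::tibble(ratio = c(0, .1, .2, .3), response = c(.1, .3, .5, .7))
#' fit_univariate(std)
#' @export
fit_univariate <- function(standards) {
  standards <- tibble::as_tibble(standards)
  check_standards(standards, 3, "A line fit")
  fit <- lm(response ~ ratio, data = standards)
  s <- suppressWarnings(summary(fit))   # exact fits trip the perfect-fit warning
  structure(list(b0 = unname(coef(fit)[1]), b1 = unname(coef(fit)[2]),
                 se = s$sigma, r2 = s$r.squared, n = nrow(standards),
                 model = fit, data = standards),
            class = "univariate_cal")
}

#' @export
print.univariate_cal <- function(x, ...) {
  cat(sprintf(
    "Linear calibration: response = %.5g + %.5g * ratio\n  se = %.4g, R2 = %.4f, n = %d\n",
    x$b0, x$b1, x$se, x$r2, x$n))
  invisible(x)
}

#' Fit the two-regime (segmented) calibration
#'
#' Electrospray ion suppression bends the ER-MS calibration into two linear
#' regimes; this fits independent lines below and above a fixed breakpoint
#' ratio, which belongs to both segments. The breakpoint is a design
#' constant (default 0.3), not estimated.
#'
#' @inheritParams fit_univariate
#' @param breakpoint Regime-change ratio, strictly inside (0, 1).
#' @return A `segmented_cal` object: `breakpoint`, `low_model` and
#'   `high_model` (each a `univariate_cal`).
#' @export
fit_segmented <- function(standards, breakpoint = 0.3) {
  standards <- tibble::as_tibble(standards)
  if (breakpoint <= 0 || breakpoint >= 1) {
    cp_abort("`breakpoint` must lie strictly inside (0, 1).", "config")
  }
  low <- dplyr::filter(standards, .data$ratio <= breakpoint)
  high <- dplyr::filter(standards, .data$ratio >= breakpoint)
  if (nrow(low) < 3 || nrow(high) < 3) {
    cp_abort("Each side of the breakpoint needs >= 3 points.", "config")
  }
  structure(list(breakpoint = breakpoint,
                 low_model = fit_univariate(low),
                 high_model = fit_univariate(high),
                 data = standards),
            class = "segmented_cal")
}

#' @export
print.segmented_cal <- function(x, ...) {
  cat(sprintf("Segmented calibration (breakpoint %.3g):\n", x$breakpoint))
  cat(sprintf("  low  slope %.5g (R2 %.4f)\n", x$low_model$b1, x$low_model$r2))
  cat(sprintf("  high slope %.5g (R2 %.4f), ratio %.3g\n",
              x$high_model$b1, x$high_model$r2,
              x$high_model$b1 / x$low_model$b1))
  invisible(x)
}

#' Fit a quadratic calibration
#'
#' A single degree-2 polynomial as the smooth alternative to the segmented
#' model for spanning the whole working interval despite ion suppression.
#' `se` uses n - 3 degrees of freedom.
#'
#' @inheritParams fit_univariate
#' @return A `quadratic_cal` object: `c0`, `c1`, `c2`, `se`, `r2`, `n`.
#' @export
fit_quadratic <- function(standards) {
  standards <- tibble::as_tibble(standards)
  check_standards(standards, 3, "A quadratic fit")
  if (dplyr::n_distinct(standards$ratio) < 4 || nrow(standards) < 4) {
    cp_abort("A quadratic fit needs >= 4 distinct ratios.", "rank_deficiency")
  }
  fit <- lm(response ~ ratio + I(ratio^2), data = standards)
  if (any(is.na(coef(fit)))) cp_abort("Quadratic design is rank deficient.",
                                      "rank_deficiency")
  s <- suppressWarnings(summary(fit))
  cf <- unname(coef(fit))
  structure(list(c0 = cf[1], c1 = cf[2], c2 = cf[3],
                 se = s$sigma, r2 = s$r.squared, n = nrow(standards),
                 model = fit, data = standards),
            class = "quadratic_cal")
}

#' @export
print.quadratic_cal <- function(x, ...) {
  cat(sprintf(
    "Quadratic calibration: %.5g + %.5g x + %.5g x^2\n  se = %.4g, R2 = %.4f, n = %d\n",
    x$c0, x$c1, x$c2, x$se, x$r2, x$n))
  invisible(x)
}

#' Invert a calibration model to a predicted molar ratio
#'
#' @param model A fitted `univariate_cal`, `segmented_cal` or
#'   `quadratic_cal`.
#' @param response Numeric vector of measured responses.
#' @param ... Method-specific arguments.
#' @return Predicted molar ratio(s). For a segmented model the segment
#'   whose inverse falls in its own ratio range is used; if both segments
#'   claim the response they must agree within `tol`, otherwise the
#'   inversion is ambiguous and errors. For a quadratic model the root
#'   inside \[-0.1, 1.1\] is taken; two distinct admissible roots error.
#' @examples
#' m <- fit_univariate(tibble::tibble(ratio = c(0, .1, .2, .3),
#'                                    response = c(0, .2, .4, .6)))
#' predict_ratio(m, 0.3)
#' @export
predict_ratio <- function(model, response, ...) UseMethod("predict_ratio")

#' @rdname predict_ratio
#' @export
predict_ratio.univariate_cal <- function(model, response, ...) {
  if (abs(model$b1) < 1e-12) {
    cp_abort("Slope is numerically zero; cannot invert.", "zero_slope")
  }
  (response - model$b0) / model$b1
}

#' @rdname predict_ratio
#' @param tol Agreement tolerance when both segments admit the response.
#' @export
predict_ratio.segmented_cal <- function(model, response, tol = 1e-9, ...) {
  lo_rng <- c(min(model$low_model$data$ratio), model$breakpoint)
  hi_rng <- c(model$breakpoint, max(model$high_model$data$ratio))
  eps <- 1e-8
  purrr::map_dbl(response, function(y) {
    xl <- predict_ratio(model$low_model, y)
    xh <- predict_ratio(model$high_model, y)
    ok_l <- xl >= lo_rng[1] - eps && xl <= lo_rng[2] + eps
    ok_h <- xh >= hi_rng[1] - eps && xh <= hi_rng[2] + eps
    if (ok_l && ok_h) {
      if (abs(xl - xh) > tol) {
        cp_abort(sprintf(
          "Ambiguous inversion: both segments admit response %.6g (%.6g vs %.6g).",
          y, xl, xh), "ambiguous")
      }
      (xl + xh) / 2
    } else if (ok_l) xl
    else if (ok_h) xh
    else cp_abort(sprintf("Response %.6g maps outside both segments.", y),
                  "no_admissible_root")
  })
}

#' @rdname predict_ratio
#' @export
predict_ratio.quadratic_cal <- function(model, response, tol = 1e-9, ...) {
  purrr::map_dbl(response, function(y) {
    if (abs(model$c2) < 1e-12) {
      if (abs(model$c1) < 1e-12) {
        cp_abort("Degenerate quadratic; cannot invert.", "zero_slope")
      }
      return((y - model$c0) / model$c1)
    }
    disc <- model$c1^2 - 4 * model$c2 * (model$c0 - y)
    if (disc < 0) cp_abort(sprintf("No real root for response %.6g.", y),
                           "no_admissible_root")
    roots <- (-model$c1 + c(-1, 1) * sqrt(disc)) / (2 * model$c2)
    adm <- roots[roots >= -0.1 & roots <= 1.1]
    if (length(adm) == 0) {
      cp_abort(sprintf("No root in [-0.1, 1.1] for response %.6g.", y),
               "no_admissible_root")
    }
    if (length(adm) == 2 && abs(adm[1] - adm[2]) > tol) {
      cp_abort(sprintf("Two admissible roots for response %.6g.", y),
               "ambiguous")
    }
    adm[1]
  })
}

#' Build an ER-MS calibration-standard table from SY curves
#'
#' Computes the chosen response for every standard sample of an SY-curve
#' table: the delta-SY at one voltage (`type = "delta_sy"`) or the CLS
#' unmixing coefficient over the whole curve (`type = "cls"`). Pure
#' reference curves (roles `reference_linear` / `reference_cyclic`) are
#' averaged pointwise before use.
#'
#' @param curves SY-curve tibble from [build_sy_curves()] with `role`,
#'   `ratio`, `replicate` metadata.
#' @param type Response type.
#' @param voltage Excitation voltage for the delta-SY response.
#' @return A tibble `ratio`, `replicate`, `response` (one row per
#'   standard), ready for [fit_univariate()] and friends.
#' @export
erms_standards <- function(curves, type = c("delta_sy", "cls"), voltage = 2.2) {
  type <- match.arg(type)
  if (!all(c("role", "ratio", "replicate") %in% names(curves))) {
    cp_abort("`curves` must carry role/ratio/replicate metadata.", "format")
  }
  ref_cyc <- average_sy_curves(dplyr::filter(curves, .data$role == "reference_cyclic"))
  if (nrow(ref_cyc) == 0) cp_abort("No pure cyclic reference curves.", "config")
  std <- dplyr::filter(curves, .data$role == "standard")
  if (type == "cls") {
    ref_lin <- average_sy_curves(dplyr::filter(curves, .data$role == "reference_linear"))
    if (nrow(ref_lin) == 0) cp_abort("No pure linear reference curves.", "config")
  }
  std |>
    dplyr::group_by(.data$ratio, .data$replicate) |>
    dplyr::group_modify(function(d, key) {
      resp <- if (type == "delta_sy") {
        delta_sy_response(d, ref_cyc, voltage)
      } else {
        cls_coefficient(d, ref_lin, ref_cyc)$a
      }
      tibble::tibble(response = resp)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$ratio, .data$replicate)
}
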