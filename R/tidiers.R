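#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for fitted calibration objects
#'
#' Broom-style one-row-per-term (`tidy()`) and one-row-per-model
#' (`glance()`) summaries.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name cyclopure-tidiers
NULL

#' @rdname cyclopure-tidiers
#' @export
tidy.boltzmann_fit <- function(x, ...) {
  tibble::tibble(term = c("A1", "A2", "V0", "dV"),
                 estimate = unlist(x$params[c("A1", "A2", "V0", "dV")]))
}

#' @rdname cyclopure-tidiers
#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, sigma = sqrt(x$rss / (nrow(x$data) - 4)),
                 n = nrow(x$data), converged = x$converged)
}

#' @rdname cyclopure-tidiers
#' @export
tidy.univariate_cal <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))$coefficients
  tibble::tibble(term = c("(Intercept)", "ratio"),
                 estimate = c(x$b0, x$b1),
                 std.error = s[, "Std. Error"],
                 statistic = s[, "t value"],
                 p.value = s[, "Pr(>|t|)"])
}

#' @rdname cyclopure-tidiers
#' @export
glance.univariate_cal <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, sigma = x$se, slope = x$b1,
                 intercept = x$b0, n = x$n)
}

#' @rdname cyclopure-tidiers
#' @export
tidy.quadratic_cal <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))$coefficients
  tibble::tibble(term = c("(Intercept)", "ratio", "ratio^2"),
                 estimate = c(x$c0, x$c1, x$c2),
                 std.error = s[, "Std. Error"],
                 statistic = s[, "t value"],
                 p.value = s[, "Pr(>|t|)"])
}

#' @rdname cyclopure-tidiers
#' @export
glance.quadratic_cal <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, sigma = x$se, n = x$n)
}

#' @rdname cyclopure-tidiers
#' @export
tidy.segmented_cal <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$low_model), segment = "low", .before = 1),
    dplyr::mutate(tidy(x$high_model), segment = "high", .before = 1))
}

#' @rdname cyclopure-tidiers
#' @export
glance.segmented_cal <- function(x, ...) {
  tibble::tibble(breakpoint = x$breakpoint,
                 slope_low = x$low_model$b1, slope_high = x$high_model$b1,
                 slope_ratio = x$high_model$b1 / x$low_model$b1,
                 r.squared_low = x$low_model$r2,
                 r.squared_high = x$high_model$r2,
                 n = nrow(x$data))
}

#' @rdname cyclopure-tidiers
#' @export
tidy.cls_fit <- function(x, ...) {
  tibble::tibble(term = "a", estimate = x$a)
}

#' @rdname cyclopure-tidiers
#' @export
glance.cls_fit <- function(x, ...) {
  tibble::tibble(a = x$a, rss = x$rss, n = nrow(x$residuals))
}

#' @rdname cyclopure-tidiers
#' @export
tidy.pls_cal <- function(x, ...) {
  tibble::tibble(n_lv = x$cv$n_lv, rmsecv = x$cv$rmsecv,
                 selected = x$cv$n_lv == x$n_lv)
}

#' @rdname cyclopure-tidiers
#' @export
glance.pls_cal <- function(x, ...) {
  tibble::tibble(n_lv = x$n_lv, rmsec = x$rmsec, rmsecv = x$rmsecv,
                 bias = x$bias, r2_cal = x$r2_cal, r2_cv = x$r2_cv,
                 n = length(x$y))
}
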