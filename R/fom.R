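#' Fit errors of calibration predictions
#'
#' Elementwise difference between predicted and reference molar ratios,
#' plus percentage errors where the reference is nonzero (a percentage at
#' reference 0 is undefined and reported as `NA`).
#'
#' @param predicted,reference Equal-length numeric vectors.
#' @return Tibble `reference`, `predicted`, `error`, `pct_error`.
#' @examples
#' fit_errors(c(0.12, 0.28), c(0.10, 0.30))
#' @export
fit_errors <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    cp_abort("`predicted` and `reference` lengths differ.", "format")
  }
  err <- predicted - reference
  tibble::tibble(reference = reference, predicted = predicted, error = err,
                 pct_error = ifelse(reference != 0, 100 * err / reference,
                                    NA_real_))
}

#' Root-mean-square error of calibration
#'
#' `sqrt(sum(e_i^2) / n)` with the divisor equal to the number of
#' calibration standards n (all replicates counted), not n minus the
#' parameter count.
#'
#' @param errors Numeric vector of fit errors, or a data frame with an
#'   `error` column (as from [fit_errors()]).
#' @return The RMSEC.
#' @examples
#' rmsec(c(0.01, -0.02, 0.02))
#' @export
rmsec <- function(errors) {
  if (is.data.frame(errors)) errors <- errors$error
  if (length(errors) == 0) cp_abort("No fit errors supplied.", "config")
  sqrt(sum(errors^2) / length(errors))
}

#' Detection limit from a univariate calibration line
#'
#' `LD = factor * se / |b1|`, with `se` the residual standard deviation of
#' the calibration line and `b1` its slope. The default factor 3.3
#' corresponds to false-positive and false-negative probabilities of 0.05
#' each.
#'
#' @param model A fitted `univariate_cal`, or `NULL` when `se` and `b1`
#'   are given directly.
#' @param factor Multiplier on `se / |b1|`.
#' @param se,b1 Residual standard deviation and slope (used when `model`
#'   is `NULL`).
#' @return The detection limit, in molar-ratio units.
#' @examples
#' lod_univariate(se = 0.01, b1 = 0.5)
#' @export
lod_univariate <- function(model = NULL, factor = 3.3, se = NULL, b1 = NULL) {
  if (!is.null(model)) {
    stopifnot(inherits(model, "univariate_cal"))
    se <- model$se
    b1 <- model$b1
  }
  if (is.null(se) || is.null(b1)) {
    cp_abort("Give either `model` or both `se` and `b1`.", "config")
  }
  if (b1 == 0) cp_abort("Zero slope: detection limit undefined.", "zero_slope")
  factor * se / abs(b1)
}

#' Detection limit of a multivariate calibration
#'
#' The multivariate analogue of the calibration-line rule:
#' `LD = factor * RMSEC`, the RMSEC playing the role of the residual
#' standard deviation.
#'
#' @param rmsec_value RMSEC of the multivariate model (>= 0).
#' @param factor Multiplier, default 3.3.
#' @return The detection limit.
#' @examples
#' lod_multivariate(0.036)
#' @export
lod_multivariate <- function(rmsec_value, factor = 3.3) {
  if (rmsec_value < 0) cp_abort("RMSEC cannot be negative.", "config")
  factor * rmsec_value
}

#' Pooled intermediate precision of replicate predictions
#'
#' Pools the replicate variance of the predicted molar ratio across
#' calibration standards, weighting each standard's Bessel-corrected
#' variance by its degrees of freedom, and reports the result as a
#' standard deviation:
#' `sqrt( sum_g (n_g - 1) s_g^2 / sum_g (n_g - 1) )`.
#'
#' @param predictions Data frame with a grouping column (default `ratio`)
#'   and a predicted-value column (default `predicted`).
#' @param group_col,value_col Column names.
#' @return The pooled standard deviation.
#' @examples
#' intermediate_precision(tibble::tibble(
#'   ratio = rep(c(0.1, 0.2), each = 3),
#'   predicted = c(0.09, 0.11, 0.10, 0.21, 0.19, 0.20)))
#' @export
intermediate_precision <- function(predictions, group_col = "ratio",
                                   value_col = "predicted") {
  if (!all(c(group_col, value_col) %in% names(predictions))) {
    cp_abort("Missing grouping or value column.", "format")
  }
  g <- predictions |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_col))) |>
    dplyr::summarise(n = dplyr::n(), v = var(.data[[value_col]]),
                     .groups = "drop")
  if (any(g$n < 2)) {
    cp_abort("Every calibration standard needs >= 2 replicates.",
             "singleton_group")
  }
  sqrt(sum((g$n - 1) * g$v) / sum(g$n - 1))
}

#' One row of the figures-of-merit comparison
#'
#' Bundles a calibration model's predictions with its summary statistics
#' into one entry of the cross-platform comparison table. RMSEC, the
#' per-standard fit errors, the pooled intermediate precision and n are
#' computed here from the predictions; R2, RMSECV and the detection limit
#' are taken from the fitted model or supplied.
#'
#' @param technique `"ERMS"` or `"IR"`.
#' @param model_type Label: `"univariate"`, `"CLS"`, `"PLS"`,
#'   `"segmented"` or `"quadratic"`.
#' @param predictions Tibble with `ratio`, `replicate`, `predicted`.
#' @param r2 Coefficient of determination of the calibration.
#' @param lod Detection limit; see [lod_univariate()]/[lod_multivariate()].
#' @param rmsecv Cross-validated error, if available.
#' @param lod_alt Optional second detection-limit estimate computed by the
#'   other rule (e.g. `3.3 * RMSEC` alongside the calibration-line rule),
#'   kept distinct in the report.
#' @param linearity_interval Length-2 numeric; defaults to (0, 0.3) for
#'   ER-MS entries and (0, 1) for IR entries.
#' @return A `fom_entry` object.
#' @export
fom_entry <- function(technique = c("ERMS", "IR"),
                      model_type = c("univariate", "CLS", "PLS", "segmented",
                                     "quadratic"),
                      predictions, r2, lod, rmsecv = NA_real_,
                      lod_alt = NA_real_, linearity_interval = NULL) {
  technique <- match.arg(technique)
  model_type <- match.arg(model_type)
  if (is.null(predictions) || nrow(predictions) == 0 ||
      !all(c("ratio", "predicted") %in% names(predictions))) {
    cp_abort(sprintf("Entry %s/%s is missing predictions.", technique,
                     model_type), "missing_predictions")
  }
  linearity_interval <- linearity_interval %||%
    if (technique == "ERMS") c(0, 0.3) else c(0, 1)
  errs <- fit_errors(predictions$predicted, predictions$ratio)
  per_standard <- dplyr::bind_cols(
    predictions[intersect(c("ratio", "replicate"), names(predictions))],
    errs[c("predicted", "error", "pct_error")])
  structure(list(technique = technique, model_type = model_type,
                 linearity_interval = linearity_interval,
                 r2 = r2, rmsec = rmsec(errs$error), rmsecv = rmsecv,
                 intermediate_precision_sd = intermediate_precision(predictions),
                 lod = lod, lod_alt = lod_alt, n = nrow(predictions),
                 per_standard = per_standard),
            class = "fom_entry")
}

#' Figures-of-merit comparison report
#'
#' Collects [fom_entry()] rows into the cross-platform performance table:
#' one row per (technique, model) with linearity interval, R2, RMSEC,
#' RMSECV, pooled intermediate precision, detection limit and n, plus the
#' per-standard fit errors behind each row.
#'
#' @param entries A list of [fom_entry()] objects (at least one).
#' @return A `fom_report`: `table` (one row per entry) and `per_standard`
#'   (long tibble of fit errors). Write/read with [write_fom_report()] and
#'   [read_fom_report()].
#' @export
fom_report <- function(entries) {
  if (inherits(entries, "fom_entry")) entries <- list(entries)
  if (length(entries) == 0) cp_abort("No fitted models to report.", "config")
  stopifnot(all(purrr::map_lgl(entries, inherits, "fom_entry")))
  table <- purrr::map_dfr(entries, function(e) {
    tibble::tibble(technique = e$technique, model = e$model_type,
                   linearity_low = e$linearity_interval[1],
                   linearity_high = e$linearity_interval[2],
                   r2 = e$r2, rmsec = e$rmsec, rmsecv = e$rmsecv,
                   intermediate_precision = e$intermediate_precision_sd,
                   lod = e$lod, lod_alt = e$lod_alt, n = e$n)
  })
  per_standard <- purrr::map_dfr(entries, function(e) {
    dplyr::mutate(e$per_standard, technique = e$technique,
                  model = e$model_type, .before = 1)
  })
  structure(list(table = table, per_standard = per_standard),
            class = "fom_report")
}

#' @export
print.fom_report <- function(x, ...) {
  cat("Figures-of-merit comparison\n")
  print(x$table)
  invisible(x)
}
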