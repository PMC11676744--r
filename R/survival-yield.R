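#' Survival yield of one MS/MS spectrum
#'
#' The survival yield is the fraction of the total ion current carried by
#' the precursor ion:
#' \deqn{SY = I_{precursor} / (I_{precursor} + \sum I_{fragment})}
#' The precursor intensity is taken as the summed intensity of all peaks
#' within `precursor_mz` +/- `window` (centroiding can split the precursor
#' over adjacent centroids), the denominator as the summed intensity of the
#' whole peak list.
#'
#' @param peaks Data frame with numeric `mz` and `intensity` columns
#'   (one centroided MS/MS spectrum).
#' @param precursor_mz Precursor m/z.
#' @param window Half-width (m/z) of the precursor window; default 0.5,
#'   matching a 1 m/z isolation window.
#' @return A survival-yield value in \[0, 1\]. A spectrum with no peak in
#'   the precursor window returns 0 with a warning (complete fragmentation
#'   or a mis-set window); a zero total ion current is an error.
#' @examples
#' compute_sy(data.frame(mz = c(2141.3, 2112.8), intensity = c(60, 40)),
#'            precursor_mz = 2141.3)
#' @export
compute_sy <- function(peaks, precursor_mz, window = 0.5) {
  if (window <= 0) cp_abort("`window` must be > 0.", "config")
  if (nrow(peaks) == 0) cp_abort("Spectrum has no peaks.", "config")
  if (any(peaks$intensity < 0)) cp_abort("Negative peak intensity.", "config")
  tic <- sum(peaks$intensity)
  if (tic <= 0) cp_abort("Total ion current is zero; SY is undefined.",
                         "undefined_sy")
  inside <- abs(peaks$mz - precursor_mz) <= window
  if (!any(inside)) {
    cp_warn(sprintf("No peak within %.3g m/z of precursor %.4f; SY set to 0.",
                    window, precursor_mz), "no_precursor_peak")
    return(0)
  }
  sum(peaks$intensity[inside]) / tic
}

#' Assemble survival-yield curves from a peak-list table
#'
#' Computes one SY value per (sample, voltage) and returns the curves
#' sorted by voltage. Metadata columns (`ratio`, `replicate`, `role`) are
#' carried through when present.
#'
#' @param peaks Peak-list tibble as produced by [simulate_erms_dataset()]
#'   or [read_peaks_csv()]: `sample_id`, `voltage_V`, `mz`, `intensity`
#'   and optionally `is_precursor`.
#' @param precursor_mz Precursor m/z; if `NULL`, inferred from the rows
#'   flagged `is_precursor == 1` (must be a single m/z).
#' @param window Precursor half-window passed to [compute_sy()].
#' @return A tibble with columns `sample_id`, (metadata), `voltage_V`, `sy`,
#'   one row per voltage, sorted within each sample. A duplicated voltage
#'   within a sample is an error naming the voltage.
#' @export
build_sy_curves <- function(peaks, precursor_mz = NULL, window = 0.5) {
  need <- c("sample_id", "voltage_V", "mz", "intensity")
  if (!all(need %in% names(peaks))) {
    cp_abort(paste("Peak table must have columns:",
                   paste(need, collapse = ", ")), "format")
  }
  if (is.null(precursor_mz)) {
    if (!"is_precursor" %in% names(peaks)) {
      cp_abort("Give `precursor_mz` or an `is_precursor` column.", "config")
    }
    pm <- unique(peaks$mz[peaks$is_precursor == 1])
    if (length(pm) != 1) {
      cp_abort("Flagged precursor m/z is not unique; pass `precursor_mz`.",
               "config")
    }
    precursor_mz <- pm
  }
  meta <- intersect(c("role", "ratio", "replicate"), names(peaks))
  # each (sample, voltage) holds one spectrum; a repeated m/z channel there
  # means two spectra were recorded at the same voltage
  spectra_per_cell <- peaks |>
    dplyr::count(.data$sample_id, .data$voltage_V, .data$mz) |>
    dplyr::filter(.data$n > 1)
  if (nrow(spectra_per_cell) > 0) {
    bad <- spectra_per_cell$voltage_V[1]
    cp_abort(sprintf("Duplicate spectrum at voltage %.4g V for sample '%s'.",
                     bad, spectra_per_cell$sample_id[1]), "duplicate_voltage")
  }
  peaks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("sample_id", meta, "voltage_V")))) |>
    dplyr::summarise(
      sy = compute_sy(dplyr::pick("mz", "intensity"),
                      precursor_mz = precursor_mz, window = window),
      .groups = "drop") |>
    dplyr::arrange(.data$sample_id, .data$voltage_V)
}

#' Fit a Boltzmann sigmoid to a survival-yield curve
#'
#' Least-squares fit of
#' `SY(V) = A2 + (A1 - A2) / (1 + exp((V - V0) / dV))`
#' by Levenberg--Marquardt. Starting values follow the usual breakdown-curve
#' heuristic: `A1 = max(sy)`, `A2 = min(sy)`, `V0` at the voltage whose SY
#' is nearest the midpoint, `dV` a tenth of the voltage span.
#'
#' @param curve Data frame with `voltage_V` and `sy` columns (>= 4 points).
#' @param init Optional [boltzmann_params()] starting values.
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the relative RSS change.
#' @return A `boltzmann_fit` object: `params` ([boltzmann_params()]), `rss`,
#'   `fitted`, `residuals`, `data`, `converged`. Supports [predict()],
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' cfg <- erms_sim_config(noise_sd_rel = 0, seed = 1)
#' curve <- tibble::tibble(voltage_V = cfg$voltage_grid,
#'                         sy = boltzmann_sy(cfg$voltage_grid, cfg$boltzmann_cyclic))
#' fit_boltzmann(curve)$params$V0
#' @export
fit_boltzmann <- function(curve, init = NULL, max_iter = 200, tol = 1e-10) {
  if (nrow(curve) < 4) cp_abort("Need at least 4 points to fit.", "config")
  v <- curve$voltage_V
  sy <- curve$sy
  if (diff(range(sy)) < 1e-8) {
    cp_abort("Curve is flat: no inflection, Boltzmann fit is degenerate.",
             "degenerate_fit")
  }
  if (is.null(init)) {
    A1 <- max(sy); A2 <- min(sy)
    mid <- (A1 + A2) / 2
    init <- boltzmann_params(A1 = A1, A2 = A2,
                             V0 = v[which.min(abs(sy - mid))],
                             dV = diff(range(v)) / 10)
  }
  start <- c(A1 = init$A1, A2 = init$A2, V0 = init$V0, dV = init$dV)
  resid_fn <- function(par) {
    sy - (par[2] + (par[1] - par[2]) / (1 + exp((v - par[3]) / par[4])))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = max_iter, ftol = tol)),
    error = function(e) {
      cp_abort(paste0("Boltzmann fit failed: ", conditionMessage(e)),
               "nonconvergence", best = init)
    })
  if (!fit$info %in% 1:4) {
    cp_abort(sprintf("Boltzmann fit did not converge in %d iterations (%s).",
                     max_iter, fit$message),
             "nonconvergence", best = as.list(fit$par))
  }
  est <- as.list(fit$par)
  # a mirrored solution (A1 < A2 with dV < 0) is the same sigmoid; canonicalise
  if (est$A1 < est$A2) {
    est <- list(A1 = est$A2, A2 = est$A1, V0 = est$V0, dV = -est$dV)
  }
  if (est$dV <= 0) {
    cp_abort("Fitted width dV <= 0: curve is not a decreasing sigmoid.",
             "degenerate_fit", best = est)
  }
  params <- boltzmann_params(est$A1, est$A2, est$V0, est$dV)
  fitted <- boltzmann_sy(v, params)
  res <- sy - fitted
  structure(list(params = params, rss = sum(res^2), fitted = fitted,
                 residuals = res,
                 data = tibble::tibble(voltage_V = v, sy = sy),
                 converged = TRUE),
            class = "boltzmann_fit")
}

#' @export
predict.boltzmann_fit <- function(object, voltage = NULL, ...) {
  voltage <- voltage %||% object$data$voltage_V
  boltzmann_sy(voltage, object$params)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat("Boltzmann survival-yield fit\n")
  cat(sprintf("  A1 = %.4f  A2 = %.4f  V0 = %.4f V  dV = %.4f V\n",
              x$params$A1, x$params$A2, x$params$V0, x$params$dV))
  cat(sprintf("  RSS = %.3g on %d points\n", x$rss, nrow(x$data)))
  invisible(x)
}

#' Read a survival-yield value off a curve
#'
#' @param curve Data frame with `voltage_V` and `sy` (one sample).
#' @param v Query excitation voltage; must lie within the curve's span.
#' @param mode `"measured"` looks up the stored value at the matching grid
#'   voltage (match required within `tol`); `"fitted"` evaluates a
#'   Boltzmann fit at `v`.
#' @param fit Optional pre-computed [fit_boltzmann()] result (fitted mode);
#'   fitted on the fly when absent.
#' @param tol Voltage matching tolerance for measured mode.
#' @return The SY value at `v`.
#' @export
sy_at_voltage <- function(curve, v, mode = c("measured", "fitted"),
                          fit = NULL, tol = 1e-9) {
  mode <- match.arg(mode)
  if (v < min(curve$voltage_V) - tol || v > max(curve$voltage_V) + tol) {
    cp_abort(sprintf("Voltage %.4g V outside the curve span [%.4g, %.4g].",
                     v, min(curve$voltage_V), max(curve$voltage_V)),
             "extrapolation")
  }
  if (mode == "measured") {
    i <- which.min(abs(curve$voltage_V - v))
    if (abs(curve$voltage_V[i] - v) > tol) {
      cp_abort(sprintf("No grid voltage within %.1g V of %.4g V.", tol, v),
               "no_grid_match")
    }
    curve$sy[i]
  } else {
    fit <- fit %||% fit_boltzmann(curve)
    boltzmann_sy(v, fit$params)
  }
}

#' Pointwise-average replicate SY curves
#'
#' Averages the SY of replicate curves voltage by voltage, as done when
#' forming the pure-component reference curves for spectral unmixing.
#'
#' @param curves SY-curve tibble (several samples on one voltage grid).
#' @return A tibble `voltage_V`, `sy` with the replicate mean per voltage.
#' @export
average_sy_curves <- function(curves) {
  curves |>
    dplyr::group_by(.data$voltage_V) |>
    dplyr::summarise(sy = mean(.data$sy), .groups = "drop") |>
    dplyr::arrange(.data$voltage_V)
}
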