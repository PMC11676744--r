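#' Normalise spectra to unit mean absorbance
#'
#' Divides each spectrum by its own mean absorbance, removing overall
#' intensity differences between depositions; the output mean is exactly 1.
#'
#' @param spectra Long IR tibble (`sample_id`, `wavenumber_cm1`,
#'   `absorbance`).
#' @return The tibble with `absorbance` rescaled per sample.
#' @export
normalise_mean <- function(spectra) {
  spectra |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      m <- mean(d$absorbance)
      if (abs(m) < 1e-300) {
        cp_abort(sprintf("Spectrum '%s' has zero mean absorbance.", key$sample_id),
                 "zero_mean")
      }
      dplyr::mutate(d, absorbance = .data$absorbance / m)
    }) |>
    dplyr::ungroup()
}

# trapezoidal integral of (x, y) over [w1, w2] with interpolated endpoints
trapz_window <- function(x, y, w1, w2) {
  ends <- approx(x, y, xout = c(w1, w2))$y
  inside <- x > w1 & x < w2
  xs <- c(w1, x[inside], w2)
  ys <- c(ends[1], y[inside], ends[2])
  sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
}

#' Band area of one spectrum
#'
#' Trapezoidal integral of the absorbance over a wavenumber window, with
#' linearly interpolated window endpoints. The default window covers the
#' linear-peptide-specific alkyne/azide band at 2040--2170 cm-1.
#'
#' @param wavenumbers,absorbance Numeric vectors (increasing grid).
#' @param window Two wavenumbers; must lie inside the grid span.
#' @return The area in absorbance * cm-1.
#' @export
band_area <- function(wavenumbers, absorbance, window = c(2040, 2170)) {
  if (length(wavenumbers) != length(absorbance)) {
    cp_abort("Grid and absorbance lengths differ.", "format")
  }
  if (min(window) < min(wavenumbers) || max(window) > max(wavenumbers)) {
    cp_abort("Integration window lies outside the wavenumber grid.",
             "window_outside_grid")
  }
  trapz_window(wavenumbers, absorbance, min(window), max(window))
}

#' Band areas for every spectrum of a long IR table
#'
#' @param spectra Long IR tibble; `value_col` names the intensity column to
#'   integrate (`"corrected"` after [asls_correct()], or `"absorbance"`).
#' @param window Integration window (cm-1).
#' @param value_col Column to integrate.
#' @return Tibble `sample_id`, (metadata), `response` -- ready to be used
#'   as calibration standards with `response` = band area.
#' @export
band_areas <- function(spectra, window = c(2040, 2170),
                       value_col = "corrected") {
  if (!value_col %in% names(spectra)) {
    cp_abort(sprintf("Column '%s' not found.", value_col), "format")
  }
  meta <- intersect(c("ratio", "replicate"), names(spectra))
  spectra |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("sample_id", meta)))) |>
    dplyr::summarise(
      response = band_area(.data$wavenumber_cm1, .data[[value_col]], window),
      .groups = "drop")
}
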