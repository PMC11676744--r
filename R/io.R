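# Shared CSV helpers. All dialects: comma-separated, UTF-8, "." decimal,
# mandatory header row; doubles written with full precision so a
# write -> read round trip is lossless.

check_header <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    cp_abort(sprintf("%s: missing required column(s): %s", path,
                     paste(missing, collapse = ", ")), "header")
  }
  invisible(df)
}

# coerce columns to numeric, reporting 1-based data line numbers of bad cells
check_numeric <- function(df, cols, path) {
  for (col in cols) {
    x <- df[[col]]
    if (!is.numeric(x)) {
      xn <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(xn) & !is.na(x))
      if (length(bad) > 0) {
        cp_abort(sprintf("%s: non-numeric value in column '%s' at data line %d.",
                         path, col, bad[1]), "bad_cell")
      }
      df[[col]] <- xn
    }
    if (anyNA(df[[col]])) {
      cp_abort(sprintf("%s: missing value in column '%s' at data line %d.",
                       path, col, which(is.na(df[[col]]))[1]), "bad_cell")
    }
  }
  df
}

write_csv_plain <- function(df, path) {
  # 17 significant digits round-trips IEEE doubles exactly
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- format(out[[col]], digits = 17,
                                                    trim = TRUE,
                                                    scientific = FALSE)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write peak-list CSV files
#'
#' The peak-list dialect holds one centroid per row:
#' `sample_id, replicate, voltage_V, mz, intensity, is_precursor`
#' (plus any extra metadata columns, which are preserved). Intensities
#' must be non-negative; violations are rejected with the offending line
#' number.
#'
#' @param peaks Peak tibble (e.g. from [simulate_erms_dataset()]).
#' @param path File path.
#' @return `read_peaks_csv()` returns the validated tibble;
#'   `write_peaks_csv()` returns `path` invisibly.
#' @export
write_peaks_csv <- function(peaks, path) {
  check_header(peaks, c("sample_id", "replicate", "voltage_V", "mz",
                        "intensity", "is_precursor"), "peak table")
  write_csv_plain(peaks, path)
}

#' @rdname write_peaks_csv
#' @export
read_peaks_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  check_header(df, c("sample_id", "replicate", "voltage_V", "mz",
                     "intensity", "is_precursor"), path)
  df <- check_numeric(df, c("replicate", "voltage_V", "mz", "intensity",
                            "is_precursor"), path)
  neg <- which(df$intensity < 0)
  if (length(neg) > 0) {
    cp_abort(sprintf("%s: negative intensity at data line %d.", path, neg[1]),
             "negative_intensity")
  }
  tibble::as_tibble(df)
}

#' Read and write survival-yield curve CSV files
#'
#' Dialect: `sample_id, voltage_V, sy` plus optional metadata columns
#' (`role`, `ratio`, `replicate`), which round-trip unchanged.
#'
#' @param curves SY-curve tibble from [build_sy_curves()].
#' @param path File path.
#' @return The curves tibble (read) or `path`, invisibly (write).
#' @export
write_sy_csv <- function(curves, path) {
  check_header(curves, c("sample_id", "voltage_V", "sy"), "SY table")
  write_csv_plain(curves, path)
}

#' @rdname write_sy_csv
#' @export
read_sy_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  check_header(df, c("sample_id", "voltage_V", "sy"), path)
  df <- check_numeric(df, c("voltage_V", "sy"), path)
  if (any(df$sy < 0 | df$sy > 1)) {
    cp_abort(sprintf("%s: SY outside [0, 1] at data line %d.", path,
                     which(df$sy < 0 | df$sy > 1)[1]), "bad_cell")
  }
  tibble::as_tibble(df)
}

#' Read and write IR dataset CSV matrices
#'
#' The IR matrix dialect has a `wavenumber_cm1` first column and one column
#' per averaged spectrum (named by `sample_id`), with a sidecar JSON
#' manifest recording ratios, replicates, seed and a config echo, so the
#' long metadata can be reconstructed on read.
#'
#' @param spectra Long IR tibble (`sample_id`, `ratio`, `replicate`,
#'   `wavenumber_cm1`, `absorbance`).
#' @param path CSV path; the manifest is written next to it.
#' @param manifest_path JSON manifest path (default `path` + `.json`).
#' @return Read: the long tibble. Write: `path`, invisibly.
#' @export
write_ir_csv <- function(spectra, path, manifest_path = paste0(path, ".json")) {
  check_header(spectra, c("sample_id", "ratio", "replicate", "wavenumber_cm1",
                          "absorbance"), "IR table")
  meta <- dplyr::distinct(spectra, .data$sample_id, .data$ratio,
                          .data$replicate)
  wide <- spectra |>
    dplyr::select("sample_id", "wavenumber_cm1", "absorbance") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "absorbance") |>
    dplyr::arrange(.data$wavenumber_cm1)
  write_csv_plain(wide, path)
  config <- attr(spectra, "config")
  manifest <- list(
    samples = meta,
    ratios = sort(unique(meta$ratio)),
    replicates = max(meta$replicate),
    seed = if (!is.null(config)) config$seed else NULL,
    config = if (!is.null(config)) {
      config[c("baseline_order", "baseline_scale", "noise_sd",
               "raw_spectra_per_replicate")]
    } else NULL)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_ir_csv
#' @export
read_ir_csv <- function(path, manifest_path = paste0(path, ".json")) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                 check.names = FALSE)
  check_header(df, "wavenumber_cm1", path)
  df <- check_numeric(df, names(df), path)
  if (any(diff(df$wavenumber_cm1) <= 0)) {
    cp_abort(sprintf("%s: wavenumber grid is not strictly increasing.", path),
             "non_monotone_grid")
  }
  long <- tidyr::pivot_longer(df, -"wavenumber_cm1", names_to = "sample_id",
                              values_to = "absorbance")
  if (file.exists(manifest_path)) {
    manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    long <- dplyr::left_join(long, tibble::as_tibble(manifest$samples),
                             by = "sample_id")
  }
  long |>
    dplyr::select(dplyr::any_of(c("sample_id", "ratio", "replicate")),
                  "wavenumber_cm1", "absorbance") |>
    dplyr::arrange(.data$sample_id, .data$wavenumber_cm1)
}

model_to_list <- function(model) {
  if (inherits(model, "univariate_cal")) {
    list(type = "univariate", coefficients = list(b0 = model$b0, b1 = model$b1),
         se = model$se, r2 = model$r2, n = model$n)
  } else if (inherits(model, "quadratic_cal")) {
    list(type = "quadratic",
         coefficients = list(c0 = model$c0, c1 = model$c1, c2 = model$c2),
         se = model$se, r2 = model$r2, n = model$n)
  } else if (inherits(model, "segmented_cal")) {
    list(type = "segmented", breakpoint = model$breakpoint,
         low = model_to_list(model$low_model),
         high = model_to_list(model$high_model))
  } else if (inherits(model, "pls_cal")) {
    list(type = "pls", n_lv = model$n_lv, rmsec = model$rmsec,
         rmsecv = model$rmsecv, bias = model$bias, r2_cal = model$r2_cal,
         r2_cv = model$r2_cv, n = length(model$y),
         regression_vector = unname(model$regression_vector))
  } else {
    cp_abort("Unsupported model class for JSON export.", "config")
  }
}

#' Export a fitted calibration model as JSON
#'
#' Serialises the coefficients and summary statistics (not the training
#' data) of a fitted calibration model.
#'
#' @param model A `univariate_cal`, `segmented_cal`, `quadratic_cal` or
#'   `pls_cal`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write and read a figures-of-merit report
#'
#' The summary table goes to CSV (columns as in the comparison table) and
#' the full report -- summary plus per-standard fit errors -- to JSON. The
#' CSV/JSON pair round-trips losslessly through [read_fom_report()].
#'
#' @param report A [fom_report()].
#' @param csv_path,json_path Output paths.
#' @return `read_fom_report()` returns a `fom_report`; the writer returns
#'   `csv_path`, invisibly.
#' @export
write_fom_report <- function(report, csv_path, json_path) {
  stopifnot(inherits(report, "fom_report"))
  write_csv_plain(report$table, csv_path)
  jsonlite::write_json(list(table = report$table,
                            per_standard = report$per_standard),
                       json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(csv_path)
}

#' @rdname write_fom_report
#' @export
read_fom_report <- function(json_path) {
  x <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  fix_na <- function(df) {
    # all-NA numeric columns deserialise as logical; restore their type
    num <- c("rmsecv", "lod_alt", "pct_error")
    for (col in intersect(num, names(df))) df[[col]] <- as.numeric(df[[col]])
    df
  }
  structure(list(table = fix_na(tibble::as_tibble(x$table)),
                 per_standard = fix_na(tibble::as_tibble(x$per_standard))),
            class = "fom_report")
}

#' Write a predictions CSV
#'
#' Dialect: `ratio, replicate, predicted` plus any extra columns.
#'
#' @param predictions Tibble with at least `ratio` and `predicted`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(predictions, path) {
  check_header(predictions, c("ratio", "predicted"), "predictions")
  write_csv_plain(predictions, path)
}

#' @rdname write_predictions_csv
#' @export
read_predictions_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  check_header(df, c("ratio", "predicted"), path)
  tibble::as_tibble(check_numeric(df, c("ratio", "predicted"), path))
}
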