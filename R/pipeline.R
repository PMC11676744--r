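#' Pipeline run configuration
#'
#' Fully-resolved settings for an end-to-end run of one or both
#' calibration branches. In simulation mode (the default) the inputs are
#' generated by the synthetic module; otherwise `erms_peaks_path` /
#' `ir_path` must point at existing peak-list / IR-matrix CSV files.
#'
#' @param branch Which branch(es) to run.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; overrides the seeds inside the two simulation
#'   configs so one integer drives the whole run.
#' @param erms_config,ir_config Simulation configs.
#' @param erms_design,ir_design Calibration designs.
#' @param voltage Excitation voltage of the univariate ER-MS response (V).
#' @param asls AsLS parameters ([asls_params()]) for IR preprocessing.
#' @param max_lv Latent-variable cap for the PLS calibration.
#' @param simulate Generate inputs (`TRUE`) or read them from disk.
#' @param erms_peaks_path,ir_path Input files for non-simulation mode.
#' @param quiet Suppress progress messages.
#' @return A `run_config` object.
#' @export
run_config <- function(branch = c("both", "erms", "ir"),
                       out_dir = file.path(tempdir(), "cyclopure_run"),
                       seed = 1L,
                       erms_config = erms_sim_config(),
                       ir_config = ir_sim_config(),
                       erms_design = cyclopure::erms_design(),
                       ir_design = cyclopure::ir_design(),
                       voltage = 2.2,
                       asls = asls_params(),
                       max_lv = 10,
                       simulate = TRUE,
                       erms_peaks_path = NULL,
                       ir_path = NULL,
                       quiet = FALSE) {
  branch <- match.arg(branch)
  erms_config$seed <- as.integer(seed)
  ir_config$seed <- as.integer(seed) + 1L
  if (!simulate) {
    if (branch %in% c("both", "erms") &&
        (is.null(erms_peaks_path) || !file.exists(erms_peaks_path))) {
      cp_abort("Non-simulation mode needs an existing `erms_peaks_path`.",
               "config")
    }
    if (branch %in% c("both", "ir") &&
        (is.null(ir_path) || !file.exists(ir_path))) {
      cp_abort("Non-simulation mode needs an existing `ir_path`.", "config")
    }
  }
  if (voltage < min(erms_config$voltage_grid) ||
      voltage > max(erms_config$voltage_grid)) {
    cp_abort("`voltage` lies outside the excitation-voltage grid.", "config")
  }
  structure(list(branch = branch, out_dir = out_dir, seed = as.integer(seed),
                 erms_config = erms_config, ir_config = ir_config,
                 erms_design = erms_design, ir_design = ir_design,
                 voltage = voltage, asls = asls, max_lv = max_lv,
                 simulate = simulate, erms_peaks_path = erms_peaks_path,
                 ir_path = ir_path, quiet = quiet),
            class = "run_config")
}

log_msg <- function(quiet, ...) if (!quiet) message("[cyclopure] ", sprintf(...))

run_erms_branch <- function(config, out_dir) {
  q <- config$quiet
  stage <- "erms/simulate"
  tryCatch({
    peaks <- if (config$simulate) {
      log_msg(q, "simulating ER-MS peak lists (seed %d, suppression %s r=%g)",
              config$erms_config$seed, config$erms_config$suppression_model,
              config$erms_config$suppression_r)
      simulate_erms_dataset(config$erms_config, config$erms_design)
    } else {
      read_peaks_csv(config$erms_peaks_path)
    }
    peaks_path <- file.path(out_dir, "erms_peaks.csv")
    write_peaks_csv(peaks, peaks_path)

    stage <- "erms/survival_yield"
    log_msg(q, "building SY curves (precursor window 0.5 m/z)")
    curves <- build_sy_curves(peaks)
    sy_path <- file.path(out_dir, "erms_sy_curves.csv")
    write_sy_csv(curves, sy_path)

    stage <- "erms/calibrate"
    log_msg(q, "univariate calibration at %.2f V; CLS over the full grid",
            config$voltage)
    std_uni <- erms_standards(curves, "delta_sy", voltage = config$voltage)
    std_cls <- erms_standards(curves, "cls")
    m_uni <- fit_univariate(std_uni)
    m_cls <- fit_univariate(std_cls)

    stage <- "erms/predict"
    pred_uni <- dplyr::mutate(std_uni,
                              predicted = predict_ratio(m_uni, .data$response))
    pred_cls <- dplyr::mutate(std_cls,
                              predicted = predict_ratio(m_cls, .data$response))
    write_model_json(m_uni, file.path(out_dir, "erms_univariate_model.json"))
    write_model_json(m_cls, file.path(out_dir, "erms_cls_model.json"))
    write_predictions_csv(pred_uni,
                          file.path(out_dir, "erms_univariate_predictions.csv"))
    write_predictions_csv(pred_cls,
                          file.path(out_dir, "erms_cls_predictions.csv"))

    entries <- list(
      fom_entry("ERMS", "univariate", pred_uni, r2 = m_uni$r2,
                lod = lod_univariate(m_uni)),
      # CLS detection limit by both rules, labelled distinctly
      fom_entry("ERMS", "CLS", pred_cls, r2 = m_cls$r2,
                lod = lod_univariate(m_cls),
                lod_alt = lod_multivariate(rmsec(
                  fit_errors(pred_cls$predicted, pred_cls$ratio)))))
    list(entries = entries,
         files = c(peaks_path, sy_path,
                   file.path(out_dir, c("erms_univariate_model.json",
                                        "erms_cls_model.json",
                                        "erms_univariate_predictions.csv",
                                        "erms_cls_predictions.csv"))))
  }, error = function(e) {
    if (inherits(e, "cyclopure_error_stage")) stop(e)
    cp_abort(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)),
             "stage", parent = e)
  })
}

run_ir_branch <- function(config, out_dir) {
  q <- config$quiet
  stage <- "ir/simulate"
  tryCatch({
    spectra <- if (config$simulate) {
      log_msg(q, "simulating IR spectra (seed %d, %d raw per replicate)",
              config$ir_config$seed, config$ir_config$raw_spectra_per_replicate)
      simulate_ir_dataset(config$ir_config, config$ir_design)
    } else {
      read_ir_csv(config$ir_path)
    }
    ir_path <- file.path(out_dir, "ir_spectra.csv")
    write_ir_csv(spectra, ir_path)

    stage <- "ir/preprocess"
    log_msg(q, "normalising to mean absorbance; AsLS (p=%g, lambda=%g)",
            config$asls$p, config$asls$lam)
    corrected <- spectra |> normalise_mean() |> asls_correct(config$asls)

    stage <- "ir/calibrate"
    areas <- band_areas(corrected)
    m_band <- fit_univariate(areas)
    m_pls <- fit_pls(corrected, value_col = "corrected",
                     max_lv = config$max_lv)
    log_msg(q, "band-area R2 = %.3f; PLS chose %d LVs (RMSECV %.4g)",
            m_band$r2, m_pls$n_lv, m_pls$rmsecv)

    stage <- "ir/predict"
    pred_band <- dplyr::mutate(areas,
                               predicted = predict_ratio(m_band, .data$response))
    pred_pls <- dplyr::mutate(m_pls$meta, ratio = m_pls$y,
                              predicted = m_pls$fitted)
    write_model_json(m_band, file.path(out_dir, "ir_band_model.json"))
    write_model_json(m_pls, file.path(out_dir, "ir_pls_model.json"))
    write_predictions_csv(pred_band,
                          file.path(out_dir, "ir_band_predictions.csv"))
    write_predictions_csv(pred_pls,
                          file.path(out_dir, "ir_pls_predictions.csv"))

    entries <- list(
      fom_entry("IR", "univariate", pred_band, r2 = m_band$r2,
                lod = lod_univariate(m_band)),
      fom_entry("IR", "PLS", pred_pls, r2 = m_pls$r2_cal,
                rmsecv = m_pls$rmsecv,
                lod = lod_multivariate(m_pls$rmsec)))
    list(entries = entries,
         files = c(ir_path, paste0(ir_path, ".json"),
                   file.path(out_dir, c("ir_band_model.json",
                                        "ir_pls_model.json",
                                        "ir_band_predictions.csv",
                                        "ir_pls_predictions.csv"))))
  }, error = function(e) {
    if (inherits(e, "cyclopure_error_stage")) stop(e)
    cp_abort(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)),
             "stage", parent = e)
  })
}

#' Run the full dual-platform pipeline
#'
#' Executes simulate (optional) -> survival yield / preprocessing ->
#' calibration -> prediction -> figures of merit for the requested
#' branch(es), writes every artefact (inputs, curves, models, predictions,
#' report, resolved configuration) under `config$out_dir`, and finishes
#' with a manifest listing each output file with its MD5 checksum. Two
#' runs with the same configuration produce identical manifests.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list: `report` (the [fom_report()]), `manifest`
#'   (tibble `file`, `md5`), `out_dir`.
#' @examples
#' \donttest{
#' cfg <- run_config(branch = "erms", seed = 42,
#'                   out_dir = file.path(tempdir(), "demo_run"), quiet = TRUE)
#' res <- run_pipeline(cfg)
#' res$report$table
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out_dir <- config$out_dir
  entries <- list()
  files <- character()
  if (config$branch %in% c("both", "erms")) {
    res <- run_erms_branch(config, out_dir)
    entries <- c(entries, res$entries)
    files <- c(files, res$files)
  }
  if (config$branch %in% c("both", "ir")) {
    res <- run_ir_branch(config, out_dir)
    entries <- c(entries, res$entries)
    files <- c(files, res$files)
  }
  report <- fom_report(entries)
  fom_csv <- file.path(out_dir, "fom_report.csv")
  fom_json <- file.path(out_dir, "fom_report.json")
  write_fom_report(report, fom_csv, fom_json)

  cfg_json <- file.path(out_dir, "run_config.json")
  jsonlite::write_json(
    list(branch = config$branch, seed = config$seed, voltage = config$voltage,
         simulate = config$simulate, max_lv = config$max_lv,
         asls = unclass(config$asls),
         erms_design = unclass(config$erms_design),
         ir_design = unclass(config$ir_design),
         suppression = list(model = config$erms_config$suppression_model,
                            r = config$erms_config$suppression_r,
                            breakpoint = config$erms_config$suppression_breakpoint)),
    cfg_json, auto_unbox = TRUE, digits = NA)

  files <- c(files, fom_csv, fom_json, cfg_json)
  manifest <- tibble::tibble(file = basename(files),
                             md5 = unname(tools::md5sum(files)))
  manifest <- dplyr::arrange(manifest, .data$file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  log_msg(config$quiet, "wrote %d artefacts to %s", nrow(manifest), out_dir)
  invisible(list(report = report, manifest = manifest, out_dir = out_dir))
}
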