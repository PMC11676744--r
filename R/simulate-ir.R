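#' Mid-IR simulation configuration
#'
#' Settings for the synthetic mid-infrared generator. The defaults emulate
#' reflectance micro-spectra of peptide films on the 675--4000 cm-1 range
#' sampled at 1725 points: a set of absorption bands shared by both isomers
#' (amide A/I/II, C-H stretch, fingerprint), one band specific to the
#' linear peptide in the 2040--2170 cm-1 window (overlapping alkyne and
#' azide stretches) whose amplitude scales with the linear molar ratio,
#' smooth random baseline drift from scattering, and white detector noise.
#' Each replicate is the average of `raw_spectra_per_replicate` raw spectra
#' (one per grid point of the acquisition map).
#'
#' @param wavenumber_grid Strictly increasing wavenumbers (cm-1);
#'   default 1725 points spanning 675--4000.
#' @param shared_bands Data frame of Gaussian bands (`centre`, `width`,
#'   `amplitude`) present in both isomers.
#' @param linear_band Bands specific to the linear peptide; centres must lie
#'   in 2040--2170 cm-1 and amplitudes scale linearly with the molar ratio.
#' @param baseline_order Degree of the random baseline polynomial.
#' @param baseline_scale Sd of the random polynomial coefficients
#'   (absorbance units); 0 disables drift.
#' @param noise_sd White-noise sd per raw spectrum (absorbance units).
#' @param raw_spectra_per_replicate Raw spectra averaged into one replicate
#'   spectrum (>= 1).
#' @param seed Integer seed.
#' @return An `ir_sim_config` object.
#' @seealso [simulate_ir_dataset()]
#' @export
ir_sim_config <- function(wavenumber_grid = seq(675, 4000, length.out = 1725),
                          shared_bands = default_shared_bands(),
                          linear_band = default_linear_band(),
                          baseline_order = 3,
                          baseline_scale = 0.05,
                          noise_sd = 0.02,
                          raw_spectra_per_replicate = 100,
                          seed = 1L) {
  if (length(wavenumber_grid) < 2) {
    cp_abort("`wavenumber_grid` needs at least 2 points.", "config")
  }
  if (any(diff(wavenumber_grid) <= 0)) {
    cp_abort("`wavenumber_grid` must be strictly increasing.", "config")
  }
  linear_band <- tibble::as_tibble(linear_band)
  shared_bands <- tibble::as_tibble(shared_bands)
  if (any(linear_band$centre < 2040 | linear_band$centre > 2170)) {
    cp_abort("`linear_band` centres must lie inside 2040-2170 cm-1.", "config")
  }
  if (raw_spectra_per_replicate < 1) {
    cp_abort("`raw_spectra_per_replicate` must be >= 1.", "config")
  }
  if (noise_sd < 0 || baseline_scale < 0) {
    cp_abort("`noise_sd` and `baseline_scale` must be >= 0.", "config")
  }
  structure(list(wavenumber_grid = wavenumber_grid,
                 shared_bands = shared_bands,
                 linear_band = linear_band,
                 baseline_order = as.integer(baseline_order),
                 baseline_scale = baseline_scale,
                 noise_sd = noise_sd,
                 raw_spectra_per_replicate = as.integer(raw_spectra_per_replicate),
                 seed = as.integer(seed)),
            class = "ir_sim_config")
}

#' @rdname ir_sim_config
#' @export
default_shared_bands <- function() {
  tibble::tribble(
    ~centre, ~width, ~amplitude,
    3290,    70,     0.85,   # amide A (N-H stretch)
    2935,    35,     0.30,   # aliphatic C-H stretch
    1655,    22,     1.00,   # amide I
    1545,    22,     0.60,   # amide II
    1240,    28,     0.28,   # amide III region
    1080,    38,     0.22    # backbone fingerprint
  )
}

#' @rdname ir_sim_config
#' @export
default_linear_band <- function() {
  # unresolved alkyne (C#C) + azide (N3) stretches of the open-chain isomer
  tibble::tibble(centre = 2105, width = 18, amplitude = 0.5)
}

gaussian_bands <- function(w, bands, scale = 1) {
  if (nrow(bands) == 0) return(numeric(length(w)))
  rowSums(vapply(seq_len(nrow(bands)), function(k) {
    scale * bands$amplitude[k] *
      exp(-0.5 * ((w - bands$centre[k]) / bands$width[k])^2)
  }, numeric(length(w))))
}

# noiseless band signal for molar ratio x
ir_signal_true <- function(x, config) {
  w <- config$wavenumber_grid
  gaussian_bands(w, config$shared_bands) + gaussian_bands(w, config$linear_band, x)
}

#' Simulate an averaged mid-IR calibration dataset
#'
#' For each (ratio, replicate) cell the generator draws
#' `raw_spectra_per_replicate` raw spectra -- the shared-band signal, the
#' ratio-scaled linear-peptide band, an independent smooth polynomial
#' baseline per raw spectrum and white noise -- and averages them into one
#' replicate spectrum, mirroring how a mapping acquisition averages the
#' spectra of its grid points.
#'
#' @param config An [ir_sim_config()].
#' @param design A [mixture_design()]; the default 11 levels x 3 replicates
#'   gives 33 averaged spectra on a 1725-point grid.
#' @param keep_raw Attach the raw (pre-average) spectra matrices as the
#'   `"raw"` attribute (one `n_raw x n_wavenumber` matrix per sample).
#' @return A long tibble: `sample_id`, `ratio`, `replicate`,
#'   `wavenumber_cm1`, `absorbance`; config/design attached as attributes.
#' @examples
#' spec <- simulate_ir_dataset(
#'   ir_sim_config(seed = 3, raw_spectra_per_replicate = 4),
#'   mixture_design(c(0, 0.5, 1), replicates = 2))
#' dplyr::n_distinct(spec$sample_id)
#' @export
simulate_ir_dataset <- function(config, design = ir_design(), keep_raw = FALSE) {
  stopifnot(inherits(config, "ir_sim_config"),
            inherits(design, "mixture_design"))
  samples <- design_table(design)
  w <- config$wavenumber_grid
  nw <- length(w)
  nraw <- config$raw_spectra_per_replicate
  tt <- seq(-1, 1, length.out = nw)   # scaled coordinate for the baseline
  tpow <- vapply(0:config$baseline_order, function(k) tt^k, numeric(nw))
  raws <- list()
  rows <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    with_seed(derive_seed(config$seed, i), {
      signal <- ir_signal_true(samples$ratio[i], config)
      cf <- matrix(rnorm(nraw * (config$baseline_order + 1L),
                         sd = config$baseline_scale),
                   nrow = nraw)
      base <- cf %*% t(tpow)                         # nraw x nw baselines
      noise <- matrix(rnorm(nraw * nw, sd = config$noise_sd), nrow = nraw)
      raw <- sweep(base + noise, 2, signal, "+")
      if (keep_raw) raws[[samples$sample_id[i]]] <<- raw
      tibble::tibble(sample_id = samples$sample_id[i],
                     ratio = samples$ratio[i],
                     replicate = samples$replicate[i],
                     wavenumber_cm1 = w,
                     absorbance = colMeans(raw))
    })
  })
  attr(rows, "config") <- config
  attr(rows, "design") <- design
  if (keep_raw) attr(rows, "raw") <- raws
  rows
}
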