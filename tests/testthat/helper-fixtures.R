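# Shared fixtures: small, fast configurations used across test files.

# noiseless ER-MS config (default Boltzmann pair, no intensity noise)
clean_erms_config <- function(seed = 1, ...) {
  erms_sim_config(noise_sd_rel = 0, seed = seed, ...)
}

# a short IR config: coarse grid + few raw spectra, for speed
small_ir_config <- function(seed = 1, n_grid = 400, nraw = 5, ...) {
  ir_sim_config(wavenumber_grid = seq(675, 4000, length.out = n_grid),
                raw_spectra_per_replicate = nraw, seed = seed, ...)
}

# exact Boltzmann SY curve as a one-sample tibble
exact_curve <- function(params, grid = seq(1.7, 2.9, by = 0.1),
                        sample_id = "s") {
  tibble::tibble(sample_id = sample_id, voltage_V = grid,
                 sy = boltzmann_sy(grid, params))
}

# exact mixture curve t * linear + (1 - t) * cyclic
exact_mixture <- function(t, lin, cyc) {
  tibble::tibble(sample_id = "mix", voltage_V = lin$voltage_V,
                 sy = t * lin$sy + (1 - t) * cyc$sy)
}

default_linear_curve <- function() {
  exact_curve(boltzmann_params(V0 = 2.1, dV = 0.1), sample_id = "lin")
}

default_cyclic_curve <- function() {
  exact_curve(boltzmann_params(V0 = 2.6, dV = 0.1), sample_id = "cyc")
}

# brute-force 1-D scan oracle for the CLS coefficient
cls_scan_oracle <- function(m, l, cc, lo = -0.2, hi = 1.2, step = 1e-6) {
  dm <- m - cc
  d <- l - cc
  # rss(a) = sum(dm^2) - 2 a sum(dm d) + a^2 sum(d^2); evaluate on the grid
  a_grid <- seq(lo, hi, by = step)
  rss <- sum(dm^2) - 2 * a_grid * sum(dm * d) + a_grid^2 * sum(d^2)
  a_grid[which.min(rss)]
}

# small noiseless ER-MS standards table from the generator (by response type)
noiseless_standards <- function(type = "cls", seed = 1, r = 0.483,
                                model = "piecewise", design = erms_design()) {
  cfg <- clean_erms_config(seed = seed, suppression_r = r,
                           suppression_model = model)
  curves <- build_sy_curves(simulate_erms_dataset(cfg, design))
  erms_standards(curves, type)
}
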