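test_that("compute_sy matches hand-computed precursor fractions", {
  pm <- 2141.3
  expect_equal(compute_sy(data.frame(mz = pm, intensity = 100), pm), 1)
  expect_equal(
    compute_sy(data.frame(mz = c(pm, 2000, 1800),
                          intensity = c(60, 25, 15)), pm),
    0.6)
  # precursor intensity zero inside the window, all current in fragments
  expect_equal(
    compute_sy(data.frame(mz = c(pm, 2000, 1800),
                          intensity = c(0, 40, 60)), pm),
    0)
})

test_that("compute_sy flags missing precursor and undefined TIC", {
  expect_warning(
    sy <- compute_sy(data.frame(mz = c(2000, 1800), intensity = c(40, 60)),
                     2141.3),
    class = "cyclopure_warning_no_precursor_peak")
  expect_equal(sy, 0)
  expect_error(compute_sy(data.frame(mz = 2141.3, intensity = 0), 2141.3),
               class = "cyclopure_error_undefined_sy")
})

test_that("compute_sy is invariant to intensity rescaling and decreases with added fragments", {
  pm <- 2141.3
  base <- data.frame(mz = c(pm, 2000), intensity = c(70, 30))
  s0 <- compute_sy(base, pm)
  for (c in c(0.01, 3, 1e6)) {
    scaled <- base
    scaled$intensity <- scaled$intensity * c
    expect_equal(compute_sy(scaled, pm), s0)
  }
  more <- rbind(base, data.frame(mz = 1500, intensity = 10))
  expect_lt(compute_sy(more, pm), s0)
})

test_that("build_sy_curves assembles sorted curves independent of input order", {
  pm <- 2141.3
  peaks <- tibble::tibble(
    sample_id = "s1",
    voltage_V = rep(c(2.2, 1.8, 2.0), each = 2),
    mz = rep(c(pm, 2000), 3),
    intensity = c(50, 50, 90, 10, 70, 30))
  cur <- build_sy_curves(peaks, precursor_mz = pm)
  expect_equal(cur$voltage_V, c(1.8, 2.0, 2.2))
  expect_equal(cur$sy, c(0.9, 0.7, 0.5))
  shuffled <- peaks[sample(nrow(peaks)), ]
  expect_equal(build_sy_curves(shuffled, precursor_mz = pm), cur)
})

test_that("a duplicated voltage is rejected with the voltage named", {
  pm <- 2141.3
  peaks <- tibble::tibble(sample_id = "s1",
                          voltage_V = c(2.0, 2.0),
                          mz = c(pm, pm), intensity = c(10, 20))
  expect_error(build_sy_curves(peaks, precursor_mz = pm), "2",
               class = "cyclopure_error_duplicate_voltage")
})

test_that("generator round trip: noiseless x = 0 curve equals the cyclic Boltzmann curve", {
  cfg <- clean_erms_config()
  curves <- build_sy_curves(
    simulate_erms_dataset(cfg, mixture_design(0, 1),
                          include_references = FALSE))
  expect_equal(curves$sy, boltzmann_sy(cfg$voltage_grid, cfg$boltzmann_cyclic),
               tolerance = 1e-14)
})

test_that("fit_boltzmann recovers exact-model parameters to high precision", {
  truth <- boltzmann_params(A1 = 1, A2 = 0, V0 = 2.0, dV = 0.08)
  fit <- fit_boltzmann(exact_curve(truth))
  expect_equal(fit$params$A1, 1, tolerance = 1e-6)
  expect_equal(fit$params$A2, 0, tolerance = 1e-6)
  expect_equal(fit$params$V0, 2.0, tolerance = 1e-6)
  expect_equal(fit$params$dV, 0.08, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("a flat curve is a degenerate fit", {
  flat <- tibble::tibble(voltage_V = seq(1.7, 2.9, 0.1), sy = 0.5)
  expect_error(fit_boltzmann(flat), class = "cyclopure_error_degenerate_fit")
})

test_that("on noisy data the fitted V0 agrees with a grid-search oracle", {
  truth <- boltzmann_params(V0 = 2.25, dV = 0.09)
  grid <- seq(1.7, 2.9, by = 0.1)
  withr::with_seed(42, {
    sy <- pmin(1, pmax(0, boltzmann_sy(grid, truth) + rnorm(length(grid), 0, 0.01)))
  })
  curve <- tibble::tibble(voltage_V = grid, sy = sy)
  fit <- fit_boltzmann(curve)

  # oracle: scan (V0, dV) at 1e-3 resolution, profiling A1, A2 linearly
  v0s <- seq(2.1, 2.4, by = 1e-3)
  dvs <- seq(0.05, 0.15, by = 1e-3)
  best <- c(rss = Inf, v0 = NA)
  for (dv in dvs) {
    for (v0 in v0s) {
      s <- 1 / (1 + exp((grid - v0) / dv))
      co <- stats::lm.fit(cbind(1, s), sy)$coefficients
      rss <- sum((sy - co[1] - co[2] * s)^2)
      if (rss < best["rss"]) best <- c(rss = rss, v0 = v0)
    }
  }
  expect_lt(abs(fit$params$V0 - best["v0"]), 3 * 0.01)
  expect_lt(abs(fit$params$V0 - best["v0"]), 2e-3 + 1e-6)
})

test_that("sy_at_voltage looks up, evaluates the fit, and refuses extrapolation", {
  truth <- boltzmann_params(V0 = 2.0, dV = 0.08)
  curve <- exact_curve(truth)
  expect_equal(sy_at_voltage(curve, 2.2, "measured"),
               curve$sy[curve$voltage_V == 2.2])
  fit <- fit_boltzmann(curve)
  expect_equal(sy_at_voltage(curve, truth$V0, "fitted", fit = fit),
               (fit$params$A1 + fit$params$A2) / 2, tolerance = 1e-9)
  for (v in c(1.8, 2.2, 2.6)) {
    expect_equal(sy_at_voltage(curve, v, "fitted", fit = fit),
                 sy_at_voltage(curve, v, "measured"), tolerance = 1e-6)
  }
  expect_error(sy_at_voltage(curve, 3.5, "measured"),
               class = "cyclopure_error_extrapolation")
  expect_error(sy_at_voltage(curve, 2.25, "measured"),
               class = "cyclopure_error_no_grid_match")
})

test_that("fitted cyclic V0 exceeds fitted linear V0 on noiseless data", {
  curves <- build_sy_curves(
    simulate_erms_dataset(clean_erms_config(), erms_design()))
  v0_lin <- fit_boltzmann(
    average_sy_curves(dplyr::filter(curves, role == "reference_linear")) |>
      dplyr::mutate(sample_id = "lin"))$params$V0
  v0_cyc <- fit_boltzmann(
    average_sy_curves(dplyr::filter(curves, role == "reference_cyclic")) |>
      dplyr::mutate(sample_id = "cyc"))$params$V0
  expect_gt(v0_cyc, v0_lin)
})
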