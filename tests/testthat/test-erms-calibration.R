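test_that("delta-SY response vanishes for pure cyclic and matches the convex identity", {
  lin <- default_linear_curve()
  cyc <- default_cyclic_curve()
  expect_equal(delta_sy_response(cyc, cyc, 2.2), 0)
  mix <- exact_mixture(0.3, lin, cyc)   # r = 1: a_eff = x
  expect_equal(delta_sy_response(mix, cyc, 2.2),
               0.3 * (sy_at_voltage(cyc, 2.2) - sy_at_voltage(lin, 2.2)),
               tolerance = 1e-12)
  # monotone in the molar ratio on noiseless mixtures
  resp <- vapply(seq(0, 1, 0.1),
                 function(t) delta_sy_response(exact_mixture(t, lin, cyc),
                                               cyc, 2.2),
                 numeric(1))
  expect_true(all(diff(resp) > 0))
})

test_that("CLS coefficient hits the endpoints and exact combinations", {
  lin <- default_linear_curve()
  cyc <- default_cyclic_curve()
  expect_equal(cls_coefficient(cyc, lin, cyc)$a, 0)
  expect_equal(cls_coefficient(lin, lin, cyc)$a, 1)
  fit <- cls_coefficient(exact_mixture(0.3, lin, cyc), lin, cyc)
  expect_equal(fit$a, 0.3, tolerance = 1e-12)
  expect_lt(fit$rss, 1e-24)
})

test_that("CLS is affine-equivariant, including coefficients outside [0, 1]", {
  lin <- default_linear_curve()
  cyc <- default_cyclic_curve()
  for (t in c(-0.15, 0.2, 0.5, 1, 1.2)) {
    expect_equal(cls_coefficient(exact_mixture(t, lin, cyc), lin, cyc)$a, t,
                 tolerance = 1e-10)
  }
})

test_that("CLS rss equals the sum of squared residuals and identical references error", {
  lin <- default_linear_curve()
  cyc <- default_cyclic_curve()
  withr::with_seed(3, {
    mix <- exact_mixture(0.4, lin, cyc)
    mix$sy <- mix$sy + rnorm(nrow(mix), 0, 0.02)
  })
  fit <- cls_coefficient(mix, lin, cyc)
  expect_equal(fit$rss, sum(fit$residuals$residual^2), tolerance = 1e-12)
  expect_error(cls_coefficient(mix, cyc, cyc),
               class = "cyclopure_error_indistinguishable")
  short <- dplyr::slice(lin, 1:5)
  expect_error(cls_coefficient(mix, short, cyc),
               class = "cyclopure_error_grid_mismatch")
})

test_that("closed-form CLS equals the brute-force scan on noisy mixtures", {
  lin <- default_linear_curve()
  cyc <- default_cyclic_curve()
  for (s in 1:10) {
    withr::with_seed(s, {
      t <- runif(1, -0.1, 1.1)
      mix <- exact_mixture(t, lin, cyc)
      mix$sy <- mix$sy + rnorm(nrow(mix), 0, 0.02)
    })
    a_closed <- cls_coefficient(mix, lin, cyc)$a
    a_scan <- cls_scan_oracle(mix$sy, lin$sy, cyc$sy)
    expect_lt(abs(a_closed - a_scan), 1e-6)
  }
})

test_that("fit_univariate reproduces an exact line and ignores row order", {
  std <- tibble::tibble(ratio = c(0, 0.1, 0.2, 0.3),
                        response = 2 * c(0, 0.1, 0.2, 0.3) + 0.1)
  m <- fit_univariate(std)
  expect_equal(m$b1, 2, tolerance = 1e-12)
  expect_equal(m$b0, 0.1, tolerance = 1e-12)
  expect_equal(m$se, 0, tolerance = 1e-12)
  expect_equal(m$r2, 1, tolerance = 1e-12)
  m2 <- fit_univariate(std[c(3, 1, 4, 2), ])
  expect_equal(m2$b0, m$b0)
  expect_equal(m2$b1, m$b1)
  expect_equal(m2$se, m$se)
  expect_error(fit_univariate(tibble::tibble(ratio = rep(0.2, 4),
                                             response = 1:4)),
               class = "cyclopure_error_rank_deficiency")
})

test_that("segmented fit recovers piecewise-exact lines and regime-change geometry", {
  x <- c(0, 0.1, 0.2, 0.3, 0.5, 0.7, 1)
  y <- ifelse(x <= 0.3, 0.5 * x, 0.15 + 2 * (x - 0.3))
  m <- fit_segmented(tibble::tibble(ratio = x, response = y), breakpoint = 0.3)
  expect_equal(m$low_model$b1, 0.5, tolerance = 1e-12)
  expect_equal(m$high_model$b1, 2, tolerance = 1e-12)

  # noiseless suppression responses: fitted high/low slope ratio above 2
  std <- tibble::tibble(ratio = c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.6, 0.8, 1)) |>
    dplyr::mutate(response = a_eff(ratio, 0.483))
  ms <- fit_segmented(std)
  expect_gt(ms$high_model$b1 / ms$low_model$b1, 2)

  # symmetric single-line data around a 0.5 breakpoint: equal slopes
  line <- tibble::tibble(ratio = seq(0, 1, 0.1), response = seq(0, 1, 0.1))
  meq <- fit_segmented(line, breakpoint = 0.5)
  expect_equal(meq$low_model$b1, meq$high_model$b1, tolerance = 1e-12)

  expect_error(fit_segmented(tibble::tibble(ratio = c(0, 0.1, 0.2, 0.5),
                                            response = 1:4)),
               class = "cyclopure_error_config")
})

test_that("quadratic fit recovers exact polynomials and degenerate cases", {
  x <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  m <- fit_quadratic(tibble::tibble(ratio = x, response = x^2))
  expect_equal(c(m$c0, m$c1, m$c2), c(0, 0, 1), tolerance = 1e-10)
  mc <- fit_quadratic(tibble::tibble(ratio = x, response = rep(0.7, 6)))
  expect_equal(c(mc$c1, mc$c2), c(0, 0), tolerance = 1e-10)
  expect_error(fit_quadratic(tibble::tibble(ratio = c(0, 0.1, 0.2),
                                            response = 1:3)),
               class = "cyclopure_error_rank_deficiency")
})

test_that("the quadratic misfits the suppression kink worse than the low-range line", {
  full <- tibble::tibble(ratio = c(0, 0.05, 0.1, 0.15, 0.2, 0.3,
                                   0.4, 0.5, 0.6, 0.8, 1)) |>
    dplyr::mutate(response = a_eff(ratio, 0.483))
  low_std <- dplyr::filter(full, ratio <= 0.3)
  quad <- fit_quadratic(full)
  low <- fit_univariate(low_std)
  pred_q <- predict_ratio(quad, low_std$response)
  pred_l <- predict_ratio(low, low_std$response)
  expect_gt(rmsec(pred_q - low_std$ratio), rmsec(pred_l - low_std$ratio))
})

test_that("predict_ratio inverts all model families", {
  m <- fit_univariate(tibble::tibble(ratio = c(0, 0.1, 0.2, 0.3),
                                     response = 2 * c(0, 0.1, 0.2, 0.3)))
  expect_equal(predict_ratio(m, 0.4), 0.2)

  x <- c(0, 0.1, 0.2, 0.3, 0.5, 0.7, 1)
  y <- ifelse(x <= 0.3, 0.5 * x, 0.15 + 2 * (x - 0.3))
  ms <- fit_segmented(tibble::tibble(ratio = x, response = y))
  # response exactly at the breakpoint: both segment inverses agree
  expect_equal(predict_ratio(ms, 0.15), 0.3, tolerance = 1e-9)
  expect_equal(predict_ratio(ms, c(0.025, 0.55)), c(0.05, 0.5),
               tolerance = 1e-9)

  mq <- fit_quadratic(tibble::tibble(ratio = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                                     response = c(0, 0.2, 0.4, 0.6, 0.8, 1)^2))
  expect_equal(predict_ratio(mq, 0.25), 0.5, tolerance = 1e-9)
  expect_error(predict_ratio(mq, -0.5),
               class = "cyclopure_error_no_admissible_root")
})

test_that("round trip predict_ratio(calibrate(x)) is the identity on noiseless standards", {
  std <- noiseless_standards("cls")
  m <- fit_univariate(std)
  expect_equal(predict_ratio(m, std$response), std$ratio, tolerance = 1e-9)
  std_d <- noiseless_standards("delta_sy")
  md <- fit_univariate(std_d)
  # delta-SY under the piecewise law is linear on [0, 0.3], so exact too
  expect_equal(predict_ratio(md, std_d$response), std_d$ratio,
               tolerance = 1e-9)
})

test_that("erms_standards computes one response per standard replicate", {
  curves <- build_sy_curves(
    simulate_erms_dataset(clean_erms_config(), erms_design()))
  std <- erms_standards(curves, "cls")
  expect_equal(nrow(std), 18)
  expect_equal(sort(unique(std$ratio)), c(0, 0.05, 0.1, 0.15, 0.2, 0.3))
  # noiseless CLS coefficients equal a_eff exactly
  expect_equal(std$response, a_eff(std$ratio, 0.483), tolerance = 1e-10)
})
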