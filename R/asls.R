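#' Asymmetric least squares baseline estimation
#'
#' Estimates a smooth baseline z under a spectrum y by minimising
#' \deqn{\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2}
#' with asymmetric weights updated each iteration: `w_i = p` where the
#' point lies above the current baseline (assumed peak) and `1 - p` where
#' it lies below (assumed noise). A small `p` therefore lets peaks float
#' above the baseline while the baseline hugs the signal-free regions.
#' The penalty uses second-order differences (a Whittaker smoother), and
#' the linear systems are solved sparsely.
#'
#' @param y Numeric absorbance vector (length >= 5, finite).
#' @param lam Smoothness penalty lambda (> 0); larger is stiffer.
#' @param p Asymmetry in (0, 1); typically 0.001--0.1.
#' @param max_iter Weight-iteration cap.
#' @param tol Stop when the largest weight change falls below this.
#' @return A list: `baseline`, `corrected` (= y - baseline), `weights`
#'   (final iterate), `iterations`, `converged`.
#' @examples
#' w <- seq(0, 1, length.out = 200)
#' y <- exp(-0.5 * ((w - 0.5) / 0.02)^2) + 2 * w
#' out <- asls_baseline(y, lam = 1e4, p = 0.001)
#' max(abs(out$baseline - 2 * w)) < 0.2
#' @export
asls_baseline <- function(y, lam = 1e4, p = 0.001, max_iter = 50, tol = 1e-6) {
  n <- length(y)
  if (n < 5) cp_abort("AsLS needs a grid of length >= 5.", "config")
  if (!all(is.finite(y))) cp_abort("Spectrum contains non-finite values.",
                                   "config")
  if (lam <= 0 || p <= 0 || p >= 1) {
    cp_abort("Require lam > 0 and 0 < p < 1.", "config")
  }
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  P <- lam * Matrix::crossprod(D)
  w <- rep(1, n)
  converged <- FALSE
  iterations <- max_iter
  for (it in seq_len(max_iter)) {
    z <- as.numeric(Matrix::solve(Matrix::Diagonal(n, w) + P, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (max(abs(w_new - w)) < tol) {
      converged <- TRUE
      iterations <- it
      w <- w_new
      break
    }
    w <- w_new
  }
  list(baseline = z, corrected = y - z, weights = w,
       iterations = iterations, converged = converged)
}

#' AsLS parameter set
#'
#' @param lam Smoothness penalty.
#' @param p Asymmetry.
#' @param max_iter,tol Iteration controls.
#' @return An `asls_params` object.
#' @export
asls_params <- function(lam = 1e4, p = 0.001, max_iter = 50, tol = 1e-6) {
  if (lam <= 0 || p <= 0 || p >= 1) {
    cp_abort("Require lam > 0 and 0 < p < 1.", "config")
  }
  structure(list(lam = lam, p = p, max_iter = max_iter, tol = tol),
            class = "asls_params")
}

#' Baseline-correct every spectrum of a long IR table
#'
#' @param spectra Long IR tibble (`sample_id`, `wavenumber_cm1`,
#'   `absorbance`, metadata).
#' @param params An [asls_params()] set.
#' @return The input tibble with `baseline` and `corrected` columns added.
#' @export
asls_correct <- function(spectra, params = asls_params()) {
  spectra |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$wavenumber_cm1)
      out <- asls_baseline(d$absorbance, lam = params$lam, p = params$p,
                           max_iter = params$max_iter, tol = params$tol)
      dplyr::mutate(d, baseline = out$baseline, corrected = out$corrected)
    }) |>
    dplyr::ungroup()
}

#' Tune AsLS parameters by PLS cross-validation
#'
#' Tries every (p, lambda) candidate pair: corrects all spectra, flags
#' pairs whose corrected spectra dip negative beyond `neg_tol` of the
#' maximum corrected intensity (over-stiff or over-asymmetric baselines cut
#' into peaks), fits a PLS calibration on each corrected set and keeps the
#' unflagged pair with the lowest cross-validated error.
#'
#' @param spectra Long IR tibble with `ratio` metadata (the calibration y).
#' @param p_candidates,lam_candidates Candidate values; the grid is their
#'   cross product.
#' @param max_lv Latent-variable cap for the scoring PLS models.
#' @param neg_tol Allowed negative excursion, as a fraction of the maximum
#'   corrected intensity (default 2%).
#' @param candidates Optional data frame of explicit (`p`, `lam`) pairs,
#'   overriding the cross product.
#' @return An `asls_tuning` object: `best` ([asls_params()]) and `results`
#'   (tibble of p, lam, rmsecv, n_lv, neg_frac, flagged).
#' @export
tune_asls <- function(spectra, p_candidates = c(0.1, 0.01, 0.001),
                      lam_candidates = c(1e3, 1e4, 1e5, 1e6),
                      max_lv = 10, neg_tol = 0.02, candidates = NULL) {
  grid <- if (is.null(candidates)) {
    tidyr::expand_grid(p = sort(p_candidates), lam = sort(lam_candidates))
  } else {
    dplyr::arrange(tibble::as_tibble(candidates)[c("p", "lam")],
                   .data$p, .data$lam)
  }
  if (nrow(grid) < 1) cp_abort("No candidate (p, lambda) pairs.", "config")
  results <- purrr::pmap_dfr(grid, function(p, lam) {
    corr <- asls_correct(spectra, asls_params(lam = lam, p = p))
    neg_frac <- -min(corr$corrected, 0) / max(corr$corrected)
    pls <- fit_pls(corr, value_col = "corrected", max_lv = max_lv)
    tibble::tibble(p = p, lam = lam, rmsecv = pls$rmsecv, n_lv = pls$n_lv,
                   neg_frac = neg_frac, flagged = neg_frac > neg_tol)
  })
  ok <- dplyr::filter(results, !.data$flagged)
  if (nrow(ok) == 0) {
    cp_abort(paste0(
      "Every candidate produced corrected spectra with negative excursions ",
      "beyond tolerance. Diagnostics: ",
      paste(sprintf("(p=%g, lam=%g: %.1f%%)", results$p, results$lam,
                    100 * results$neg_frac), collapse = " ")),
      "all_flagged")
  }
  best <- ok[which.min(ok$rmsecv), ]
  structure(list(best = asls_params(lam = best$lam, p = best$p),
                 results = results),
            class = "asls_tuning")
}

#' @export
print.asls_tuning <- function(x, ...) {
  cat(sprintf("AsLS tuning: best p = %g, lambda = %g\n",
              x$best$p, x$best$lam))
  print(x$results)
  invisible(x)
}
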