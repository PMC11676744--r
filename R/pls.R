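# NIPALS PLS1 on already-centred X, y. Returns weights W, loadings P,
# y-loadings q and scores T for up to `A` components (fewer if X deflates
# to numerical zero first).
pls1_nipals <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A)
  a <- 0L
  for (h in seq_len(A)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break
    w <- w / nw
    t <- X %*% w
    tt <- sum(t^2)
    if (tt < 1e-14) break
    pvec <- crossprod(X, t) / tt
    qh <- sum(y * t) / tt
    X <- X - t %*% t(pvec)
    y <- y - qh * t
    a <- h
    W[, h] <- w; P[, h] <- pvec; Tm[, h] <- t; q[h] <- qh
  }
  list(W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       scores = Tm[, seq_len(a), drop = FALSE], q = q[seq_len(a)], a = a)
}

# regression vector using the first `a` latent variables
pls1_beta <- function(fit, a) {
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  drop(W %*% solve(crossprod(P, W), fit$q[seq_len(a)]))
}

# long tibble -> list(X matrix [samples x channels], y, meta tibble),
# rows ordered so each ratio level's replicates are contiguous
spectra_to_matrix <- function(spectra, value_col) {
  need <- c("sample_id", "wavenumber_cm1", value_col)
  if (!all(need %in% names(spectra))) {
    cp_abort(paste("Spectra table must have columns:",
                   paste(need, collapse = ", ")), "format")
  }
  meta_cols <- intersect(c("ratio", "replicate"), names(spectra))
  meta <- dplyr::distinct(spectra,
                          dplyr::across(dplyr::all_of(c("sample_id", meta_cols))))
  if ("ratio" %in% meta_cols) {
    meta <- dplyr::arrange(meta, .data$ratio,
                           !!!rlang::syms(intersect("replicate", meta_cols)),
                           .data$sample_id)
  }
  wide <- spectra |>
    dplyr::select(dplyr::all_of(c("sample_id", "wavenumber_cm1", value_col))) |>
    tidyr::pivot_wider(names_from = "wavenumber_cm1",
                       values_from = dplyr::all_of(value_col))
  wide <- wide[match(meta$sample_id, wide$sample_id), ]
  X <- as.matrix(wide[, -1])
  rownames(X) <- wide$sample_id
  list(X = X, meta = meta,
       wavenumbers = as.numeric(colnames(X)))
}

resolve_blocks <- function(blocks, meta, n) {
  if (is.null(blocks)) {
    if (!"ratio" %in% names(meta)) {
      cp_abort("No `ratio` metadata: pass `blocks` explicitly.", "config")
    }
    f <- factor(meta$ratio, levels = unique(meta$ratio))
  } else if (length(blocks) == 1 && is.numeric(blocks)) {
    k <- as.integer(blocks)
    if (n %% k != 0) {
      cp_abort(sprintf(
        "%d samples cannot be split into %d contiguous equal blocks.", n, k),
        "block_scheme")
    }
    f <- factor(rep(seq_len(k), each = n %/% k))
  } else {
    if (length(blocks) != n) {
      cp_abort("`blocks` must label every sample.", "block_scheme")
    }
    f <- factor(blocks, levels = unique(blocks))
  }
  split(seq_len(n), f)
}

#' PLS1 calibration with contiguous-block cross-validation
#'
#' Mean-centred partial least squares regression of the molar ratio on the
#' full spectral matrix (NIPALS), validated by contiguous-block
#' cross-validation in which each concentration level's replicates form
#' one held-out block -- the scheme that prevents replicate leakage between
#' training and validation. The latent-variable count is chosen as the
#' smallest one attaining the minimal RMSECV.
#'
#' @param x Either a long IR tibble (with `sample_id`, `wavenumber_cm1`,
#'   `ratio` and the intensity column named by `value_col`) or a numeric
#'   matrix of spectra (samples in rows, already ordered so replicate
#'   groups are contiguous).
#' @param y Reference molar ratios; required for the matrix interface,
#'   taken from the `ratio` column otherwise.
#' @param value_col Intensity column of the long-table interface.
#' @param max_lv Largest latent-variable count to consider; capped (with a
#'   warning) at the rank of the centred X.
#' @param blocks Cross-validation blocks: `NULL` (one block per ratio
#'   level), an integer number of contiguous equal blocks (errors if the
#'   sample count is not divisible), or a length-n vector of block labels.
#' @param n_lv Force a latent-variable count instead of selecting by
#'   RMSECV.
#' @return A `pls_cal` object: `n_lv`, `x_mean`, `y_mean`, `weights`,
#'   `loadings`, `q`, `scores`, `regression_vector`, `fitted`, `cv_pred`,
#'   `rmsec`, `rmsecv`, `bias`, `r2_cal`, `r2_cv`, `cv` (per-LV RMSECV
#'   table) and the sample metadata. Supports [predict()],
#'   [generics::tidy()], [generics::glance()], [ggplot2::autoplot()].
#' @export
fit_pls <- function(x, y = NULL, value_col = "corrected", max_lv = 10,
                    blocks = NULL, n_lv = NULL) {
  if (is.matrix(x)) {
    if (is.null(y)) cp_abort("`y` is required with a matrix `x`.", "config")
    X <- x
    meta <- tibble::tibble(sample_id = rownames(x) %||%
                             sprintf("s%02d", seq_len(nrow(x))),
                           ratio = y)
    wavenumbers <- suppressWarnings(as.numeric(colnames(x)))
  } else {
    mat <- spectra_to_matrix(x, value_col)
    X <- mat$X
    meta <- mat$meta
    wavenumbers <- mat$wavenumbers
    if (is.null(y)) {
      if (!"ratio" %in% names(meta)) {
        cp_abort("No `ratio` column; supply `y`.", "config")
      }
      y <- meta$ratio
    }
  }
  n <- nrow(X)
  if (n < 3) cp_abort("Need at least 3 samples.", "config")
  if (max_lv < 1) cp_abort("`max_lv` must be >= 1.", "config")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  rank_x <- qr(Xc)$rank
  if (max_lv > rank_x) {
    cp_warn(sprintf("max_lv = %d exceeds rank %d of centred X; capped.",
                    max_lv, rank_x), "lv_capped")
    max_lv <- rank_x
  }
  folds <- resolve_blocks(blocks, meta, n)
  cv_pred <- matrix(NA_real_, n, max_lv)
  for (idx in folds) {
    Xtr <- X[-idx, , drop = FALSE]; ytr <- y[-idx]
    xm <- colMeans(Xtr); ym <- mean(ytr)
    f <- pls1_nipals(sweep(Xtr, 2, xm), ytr - ym, max_lv)
    Xte <- sweep(X[idx, , drop = FALSE], 2, xm)
    for (a in seq_len(max_lv)) {
      ae <- min(a, f$a)   # fold may support fewer components
      cv_pred[idx, a] <- ym + Xte %*% pls1_beta(f, ae)
    }
  }
  rmsecv_by_lv <- sqrt(colMeans((cv_pred - y)^2))
  if (is.null(n_lv)) {
    n_lv <- min(which(rmsecv_by_lv <= min(rmsecv_by_lv) * (1 + 1e-8) + 1e-15))
  } else if (n_lv > max_lv) {
    cp_warn("Requested n_lv exceeds the usable maximum; capped.", "lv_capped")
    n_lv <- max_lv
  }
  full <- pls1_nipals(Xc, y - y_mean, max_lv)
  n_lv <- min(n_lv, full$a)
  beta <- pls1_beta(full, n_lv)
  fitted <- drop(y_mean + Xc %*% beta)
  cvp <- cv_pred[, n_lv]
  tss <- sum((y - y_mean)^2)
  rmsec_by_lv <- vapply(seq_len(full$a), function(a) {
    sqrt(mean((drop(y_mean + Xc %*% pls1_beta(full, a)) - y)^2))
  }, numeric(1))
  structure(list(
    n_lv = n_lv, max_lv = max_lv,
    x_mean = x_mean, y_mean = y_mean,
    weights = full$W[, seq_len(n_lv), drop = FALSE],
    loadings = full$P[, seq_len(n_lv), drop = FALSE],
    q = full$q[seq_len(n_lv)],
    scores = full$scores[, seq_len(n_lv), drop = FALSE],
    regression_vector = beta,
    wavenumbers = wavenumbers,
    y = y, meta = meta, fitted = fitted, cv_pred = cvp,
    rmsec = sqrt(mean((fitted - y)^2)),
    rmsecv = rmsecv_by_lv[n_lv],
    bias = mean(cvp - y),
    r2_cal = 1 - sum((y - fitted)^2) / tss,
    r2_cv = 1 - sum((y - cvp)^2) / tss,
    cv = tibble::tibble(n_lv = seq_len(max_lv), rmsecv = rmsecv_by_lv,
                        rmsec = rmsec_by_lv[pmin(seq_len(max_lv), full$a)]),
    block_sizes = lengths(folds)),
    class = "pls_cal")
}

#' @export
predict.pls_cal <- function(object, newdata, value_col = "corrected", ...) {
  if (is.matrix(newdata)) {
    X <- newdata
    meta <- NULL
  } else {
    mat <- spectra_to_matrix(newdata, value_col)
    X <- mat$X
    meta <- mat$meta
  }
  if (ncol(X) != length(object$x_mean)) {
    cp_abort("New spectra are not on the calibration grid.", "format")
  }
  pred <- drop(object$y_mean +
                 sweep(X, 2, object$x_mean) %*% object$regression_vector)
  if (is.null(meta)) pred else dplyr::mutate(meta, predicted = pred)
}

#' @export
print.pls_cal <- function(x, ...) {
  cat(sprintf("PLS1 calibration: %d latent variables (of %d tried)\n",
              x$n_lv, x$max_lv))
  cat(sprintf("  RMSEC = %.4g  RMSECV = %.4g  bias = %.3g\n",
              x$rmsec, x$rmsecv, x$bias))
  cat(sprintf("  R2(cal) = %.4f  R2(cv) = %.4f  n = %d\n",
              x$r2_cal, x$r2_cv, length(x$y)))
  invisible(x)
}
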