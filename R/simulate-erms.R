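#' Boltzmann sigmoid parameters
#'
#' Parameter set for the four-parameter Boltzmann sigmoid
#' \deqn{SY(V) = A_2 + \frac{A_1 - A_2}{1 + \exp((V - V_0)/dV)}}
#' used to describe survival-yield breakdown curves: `A1` is the upper
#' asymptote (intact precursor at low excitation), `A2` the lower asymptote,
#' `V0` the inflection voltage and `dV` the transition width in volts.
#'
#' @param A1 Upper asymptote (survival yield at low voltage).
#' @param A2 Lower asymptote.
#' @param V0 Inflection excitation voltage (V).
#' @param dV Transition width (V); must be positive.
#' @return An object of class `boltzmann_params`.
#' @examples
#' p <- boltzmann_params(V0 = 2.1, dV = 0.1)
#' boltzmann_sy(seq(1.7, 2.9, 0.1), p)
#' @export
boltzmann_params <- function(A1 = 1, A2 = 0, V0, dV) {
  if (!is.numeric(dV) || dV <= 0) cp_abort("`dV` must be > 0.", "config")
  if (A1 <= A2) cp_abort("`A1` must exceed `A2`.", "config")
  structure(list(A1 = A1, A2 = A2, V0 = V0, dV = dV), class = "boltzmann_params")
}

#' Evaluate a Boltzmann sigmoid
#'
#' @param v Numeric vector of excitation voltages (V).
#' @param params A [boltzmann_params()] object.
#' @return Survival-yield values, same length as `v`.
#' @export
boltzmann_sy <- function(v, params) {
  params$A2 + (params$A1 - params$A2) / (1 + exp((v - params$V0) / params$dV))
}

#' Mixture calibration design
#'
#' Defines the molar ratios of linear peptide (x = n_Lin / n_Total) and the
#' replicate count of a calibration series. [erms_design()] and [ir_design()]
#' give the default designs for the two platforms: six levels spanning the
#' ion-suppression-limited linear range 0--0.3 for energy-resolved MS, and
#' eleven levels spanning the full 0--1 interval for the IR branch.
#'
#' @param ratios Numeric vector of molar ratios in \[0, 1\].
#' @param replicates Replicates per ratio (>= 1).
#' @return A `mixture_design` object.
#' @examples
#' mixture_design(c(0, 0.1, 0.3), replicates = 3)
#' @export
mixture_design <- function(ratios, replicates = 3) {
  if (!is.numeric(ratios) || length(ratios) == 0 ||
      any(ratios < 0 | ratios > 1)) {
    cp_abort("`ratios` must be numeric values in [0, 1].", "config")
  }
  if (anyDuplicated(ratios)) cp_abort("`ratios` must be distinct.", "config")
  if (replicates < 1) cp_abort("`replicates` must be >= 1.", "config")
  structure(list(ratios = sort(ratios), replicates = as.integer(replicates)),
            class = "mixture_design")
}

#' @rdname mixture_design
#' @export
erms_design <- function(replicates = 3) {
  mixture_design(c(0, 0.05, 0.1, 0.15, 0.2, 0.3), replicates)
}

#' @rdname mixture_design
#' @export
ir_design <- function(replicates = 3) {
  mixture_design(c(0, 0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5, 0.6, 0.8, 1),
                 replicates)
}

#' @rdname mixture_design
#' @param design A `mixture_design`.
#' @return `design_table()` returns a tibble with one row per
#'   (ratio, replicate) and a `sample_id` column.
#' @export
design_table <- function(design) {
  stopifnot(inherits(design, "mixture_design"))
  tidyr::expand_grid(ratio = design$ratios,
                     replicate = seq_len(design$replicates)) |>
    dplyr::mutate(sample_id = sprintf("x%05.3f_rep%d", .data$ratio,
                                      .data$replicate))
}

#' Energy-resolved MS simulation configuration
#'
#' Settings for the synthetic ER-MS generator. The defaults emulate the
#' study conditions of a caesium-cationised linear/cyclic peptide pair: an
#' excitation ladder of 1.7--2.9 V in 0.1 V steps, sigmoidal breakdown
#' curves with the cyclic isomer's inflection shifted to higher voltage, a
#' nominal precursor at 2141.3 m/z, and electrospray ion suppression of the
#' linear peptide at low molar ratios with a low-range response factor of
#' 0.483.
#'
#' Two suppression laws are available for the effective mixing coefficient
#' `a_eff(x)` that places a mixture's SY curve between the two pure-isomer
#' curves:
#' * `"piecewise"` (default): slope `suppression_r` on
#'   \[0, `suppression_breakpoint`\], then linear up to `a_eff(1) = 1`. This
#'   reproduces the two observed linear calibration regimes exactly, with a
#'   high/low slope ratio of `(1 - b r) / ((1 - b) r)` (about 2.5 at the
#'   defaults).
#' * `"rational"`: `a_eff = r x / (r x + (1 - x))`, a smooth competitive-
#'   ionisation law with derivative `r / (1 + (r - 1) x)^2`, hence initial
#'   slope `r` and terminal slope `1/r`.
#'
#' @param voltage_grid Strictly increasing excitation voltages (V).
#' @param boltzmann_linear,boltzmann_cyclic [boltzmann_params()] of the pure
#'   isomers; the cyclic inflection should sit above the linear one.
#' @param suppression_r Low-range response factor of the linear peptide,
#'   in (0, 1]. 1 means no ion suppression.
#' @param suppression_model `"piecewise"` or `"rational"` (see Details).
#' @param suppression_breakpoint Regime-change ratio for the piecewise law.
#' @param intensity_scale Total ion current per spectrum (arbitrary counts).
#' @param noise_sd_rel Relative (multiplicative) Gaussian noise sd applied
#'   to every peak intensity; intensities are truncated at zero.
#' @param n_fragments Number of fragment channels the non-surviving
#'   intensity is split over (symmetric Dirichlet split).
#' @param precursor_mz Nominal precursor m/z (label only).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An `erms_sim_config` object.
#' @seealso [simulate_erms_dataset()]
#' @export
erms_sim_config <- function(voltage_grid = seq(1.7, 2.9, by = 0.1),
                            boltzmann_linear = boltzmann_params(V0 = 2.1, dV = 0.1),
                            boltzmann_cyclic = boltzmann_params(V0 = 2.6, dV = 0.1),
                            suppression_r = 0.483,
                            suppression_model = c("piecewise", "rational"),
                            suppression_breakpoint = 0.3,
                            intensity_scale = 1e5,
                            noise_sd_rel = 0.01,
                            n_fragments = 8,
                            precursor_mz = 2141.3,
                            seed = 1L) {
  suppression_model <- match.arg(suppression_model)
  if (length(voltage_grid) == 0) cp_abort("`voltage_grid` is empty.", "config")
  if (any(diff(voltage_grid) <= 0)) {
    cp_abort("`voltage_grid` must be strictly increasing.", "config")
  }
  if (suppression_r <= 0 || suppression_r > 1) {
    cp_abort("`suppression_r` must lie in (0, 1].", "config")
  }
  if (noise_sd_rel < 0) cp_abort("`noise_sd_rel` must be >= 0.", "config")
  if (n_fragments < 1) cp_abort("`n_fragments` must be >= 1.", "config")
  if (suppression_breakpoint <= 0 || suppression_breakpoint >= 1) {
    cp_abort("`suppression_breakpoint` must lie in (0, 1).", "config")
  }
  structure(list(voltage_grid = voltage_grid,
                 boltzmann_linear = boltzmann_linear,
                 boltzmann_cyclic = boltzmann_cyclic,
                 suppression_r = suppression_r,
                 suppression_model = suppression_model,
                 suppression_breakpoint = suppression_breakpoint,
                 intensity_scale = intensity_scale,
                 noise_sd_rel = noise_sd_rel,
                 n_fragments = as.integer(n_fragments),
                 precursor_mz = precursor_mz,
                 seed = as.integer(seed)),
            class = "erms_sim_config")
}

#' Effective mixing coefficient under ion suppression
#'
#' Maps the true molar ratio x of linear peptide to the effective weight of
#' the linear SY curve in the mixture's breakdown curve. Both laws satisfy
#' `a_eff(0) = 0`, `a_eff(1) = 1`, monotonicity, and `a_eff(x) <= x` for
#' `r < 1` (suppression can only depress the linear signal).
#'
#' @param x Molar ratio(s) in \[0, 1\].
#' @param r Low-range response factor in (0, 1].
#' @param model `"piecewise"` or `"rational"`.
#' @param breakpoint Regime change point for the piecewise law.
#' @return Effective coefficient(s), same length as `x`.
#' @examples
#' a_eff(c(0, 0.15, 0.3, 1), r = 0.483)
#' @export
a_eff <- function(x, r, model = c("piecewise", "rational"), breakpoint = 0.3) {
  model <- match.arg(model)
  if (model == "rational") {
    r * x / (r * x + (1 - x))
  } else {
    hi_slope <- (1 - r * breakpoint) / (1 - breakpoint)
    ifelse(x <= breakpoint, r * x, r * breakpoint + (x - breakpoint) * hi_slope)
  }
}

sy_mixture_true <- function(x, v, config) {
  a <- a_eff(x, config$suppression_r, config$suppression_model,
             config$suppression_breakpoint)
  a * boltzmann_sy(v, config$boltzmann_linear) +
    (1 - a) * boltzmann_sy(v, config$boltzmann_cyclic)
}

# One sample's peak list over the voltage ladder (already seeded).
simulate_erms_sample <- function(x, config) {
  nv <- length(config$voltage_grid)
  nf <- config$n_fragments
  sy <- sy_mixture_true(x, config$voltage_grid, config)
  # fragment m/z channels: dominant N2 loss first, then lighter backbone ions
  frag_mz <- config$precursor_mz - 28.5 - 120 * (seq_len(nf) - 1)
  purrr::map_dfr(seq_len(nv), function(i) {
    split <- rgamma(nf, shape = 1)
    split <- split / sum(split)
    inten0 <- c(sy[i], (1 - sy[i]) * split) * config$intensity_scale
    inten <- pmax(0, inten0 * (1 + rnorm(nf + 1L, 0, config$noise_sd_rel)))
    tibble::tibble(voltage_V = config$voltage_grid[i],
                   mz = c(config$precursor_mz, frag_mz),
                   intensity = inten,
                   is_precursor = c(1L, rep(0L, nf)))
  })
}

#' Simulate an energy-resolved MS calibration dataset
#'
#' Generates centroided peak lists for every (ratio, replicate, voltage)
#' cell of a calibration design, plus (by default) pure-isomer reference
#' samples at x = 0 and x = 1 measured alongside the standards, as a
#' calibration batch would include. The precursor's intensity fraction at
#' each voltage equals the mixture survival yield
#' `a_eff(x) SY_lin(V) + (1 - a_eff(x)) SY_cyc(V)` before noise; the
#' remaining current is split over fragment channels.
#'
#' @param config An [erms_sim_config()].
#' @param design A [mixture_design()].
#' @param include_references Also simulate pure cyclic (x = 0) and pure
#'   linear (x = 1) reference samples, flagged in the `role` column.
#' @return A tibble of peaks: `sample_id`, `role`, `ratio`, `replicate`,
#'   `voltage_V`, `mz`, `intensity`, `is_precursor`, with the config and
#'   design attached as attributes.
#' @examples
#' peaks <- simulate_erms_dataset(erms_sim_config(seed = 7), erms_design())
#' dplyr::count(peaks, role)
#' @export
simulate_erms_dataset <- function(config, design, include_references = TRUE) {
  stopifnot(inherits(config, "erms_sim_config"),
            inherits(design, "mixture_design"))
  samples <- design_table(design) |> dplyr::mutate(role = "standard")
  if (include_references) {
    refs <- tidyr::expand_grid(ratio = c(0, 1),
                               replicate = seq_len(design$replicates)) |>
      dplyr::mutate(
        role = ifelse(.data$ratio == 0, "reference_cyclic", "reference_linear"),
        sample_id = sprintf("%s_rep%d",
                            ifelse(.data$ratio == 0, "ref_cyc", "ref_lin"),
                            .data$replicate))
    samples <- dplyr::bind_rows(samples, refs)
  }
  out <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    with_seed(derive_seed(config$seed, i), {
      simulate_erms_sample(samples$ratio[i], config) |>
        dplyr::mutate(sample_id = samples$sample_id[i],
                      role = samples$role[i],
                      ratio = samples$ratio[i],
                      replicate = samples$replicate[i],
                      .before = 1)
    })
  })
  attr(out, "config") <- config
  attr(out, "design") <- design
  out
}
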