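---
title: "Dual-platform calibration for linear/cyclic peptide isomer ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-platform calibration for linear/cyclic peptide isomer ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclopure)
```

`cyclopure` quantifies the molar ratio x = n_Lin / n_Total of a linear
peptide in mixtures with its isomeric click-cyclised product, by two
independent routes: energy-resolved tandem MS (survival-yield breakdown
curves) and mid-infrared spectroscopy (the alkyne/azide marker band).
This vignette is the package's account of the underlying models, the
synthetic-data generator that stands in for instrument data, every
numerical choice that was genuinely open, and what the passing tests do
and do not establish about real measurements.

## The survival-yield model

At each excitation voltage V an MS/MS spectrum yields the survival yield

$$SY(V) = \frac{I_{precursor}}{I_{precursor} + \sum I_{fragment}},$$

the precursor's share of the total ion current: 1 for an intact ion, 0
at complete fragmentation. `compute_sy()` sums all centroids within
±0.5 m/z of the precursor (half of a 1 m/z isolation window), because
centroiding can split the precursor over adjacent peaks; peak heights
are used, areas are not modelled. SY is scale-invariant in the
intensities and strictly decreasing in added fragment current.

Breakdown curves SY(V) are sigmoidal and are fitted with the
four-parameter Boltzmann form

$$SY(V) = A_2 + \frac{A_1 - A_2}{1 + \exp\!\big((V - V_0)/dV\big)},$$

the parameterisation used by common curve-fitting tools: $A_1$ and $A_2$
are the plateaus, $V_0$ the inflection voltage, $dV > 0$ the width of a
*decreasing* transition. Fitting is Levenberg–Marquardt
(`minpack.lm::nls.lm`) with heuristic starts ($A_1 = \max SY$,
$A_2 = \min SY$, $V_0$ at the voltage nearest the midpoint,
$dV = \text{span}/10$), a 200-iteration cap and a $10^{-10}$ relative
tolerance on the residual sum of squares. Two degenerate cases are
rejected explicitly rather than returned silently: a flat curve (no
inflection) and a fit whose canonicalised width is non-positive. A
mirrored optimum ($A_1 < A_2$ with $dV < 0$, the same sigmoid) is
canonicalised before validation. The noisy-data tests corroborate the
optimiser against a brute-force (V₀, dV) grid search at $10^{-3}$
resolution with the plateaus profiled out linearly.

## ER-MS calibration

The cyclic isomer fragments at higher voltage, so a mixture's curve sits
between the pure-component curves. Two responses are calibrated against
x, using pure references (x = 0, x = 1) measured in the same batch and
averaged pointwise across replicates:

* **ΔSY at one voltage** (default 2.2 V, the most discriminating voltage
  for the default curve pair): $SY_{cyc}(V^*) - SY_{mix}(V^*)$, read from
  the measured grid (an exact grid match within $10^{-9}$ V is required;
  evaluating the Boltzmann fit instead is an explicit option, never a
  silent fallback).
* **CLS over the whole curve**:
  $\mathbf{SY}_{mix} = a\,\mathbf{SY}_{lin} + (1-a)\,\mathbf{SY}_{cyc} + \mathbf{e}$,
  with the closed form $a = \langle m-c,\, l-c\rangle / \lVert l-c \rVert^2$.
  The full common voltage grid is used (a sub-range is configurable for
  sensitivity studies). `a` is deliberately **not clipped** to [0, 1]:
  out-of-range coefficients diagnose noise or reference failure and must
  reach the report.

Electrospray ion suppression makes the response nonlinear in x over the
full interval: the calibration shows a shallow linear regime at low x
and a steeper one above a regime-change ratio near 0.3. Three model
families handle this: the straight line on the low range (the regime of
practical interest, traces of linear precursor), a segmented model with
the breakpoint *fixed* at 0.3 (estimating it is out of scope; the
breakpoint belongs to both segments, and inversion at the breakpoint
response must agree between segments within $10^{-9}$ on continuous
data), and a single quadratic over the whole interval. Inversion picks
the segment whose inverse lands in its own ratio range, or the quadratic
root inside [−0.1, 1.1]; genuinely ambiguous responses raise errors
rather than guessing. The residual standard deviation uses n − 2 degrees
of freedom (n − 3 for the quadratic) — the conventional OLS standard
error, chosen because the source of the "standard deviation of the
residuals" convention does not specify the divisor.

## The ER-MS generator and the suppression law

The generator draws, per (ratio, replicate, voltage), one centroided
peak list whose precursor fraction equals the mixture survival yield

$$SY_{mix}(V) = a_{\mathrm{eff}}(x)\, SY_{lin}(V) + \big(1 -
a_{\mathrm{eff}}(x)\big)\, SY_{cyc}(V),$$

with defaults that emulate the study conditions for a caesium-cationised
peptide pair: voltage ladder 1.7–2.9 V in 0.1 V steps, nominal precursor
at 2141.3 m/z, linear-isomer inflection at 2.1 V and cyclic at 2.6 V
(width 0.1 V each) — with these curves the linear peptide is almost
fully fragmented at 2.5 V while the cyclic one barely is, and 2.2 V is
the most discriminating single voltage.

The effective coefficient $a_{\mathrm{eff}}$ encodes ion suppression of
the linear peptide. Two laws are implemented:

* **piecewise-linear** (default): slope r on [0, 0.3], then linear up to
  $a_{\mathrm{eff}}(1) = 1$. With the default response factor r = 0.483
  the high/low slope ratio is $(1 - 0.3r)/(0.7r) \approx 2.5$.
* **rational**: $a_{\mathrm{eff}} = rx / (rx + 1 - x)$, a smooth
  competitive-ionisation law with derivative $r/(1 + (r-1)x)^2$ (slope r
  at x = 0, 1/r at x = 1).

The piecewise law is the default because the phenomenon being emulated
is *two linear calibration regimes*: a generator whose low-range response
is exactly linear with slope r keeps the fitted low-range calibration
slope equal to r (the rational law, though physically appealing, is
curved enough that an OLS fit over the 0–0.3 design returns ≈ 0.57 for
r = 0.483 — it would misstate the very quantity the low-range
calibration estimates). Both laws satisfy $a_{\mathrm{eff}}(0)=0$,
$a_{\mathrm{eff}}(1)=1$, monotonicity, and
$a_{\mathrm{eff}}(x) \le x$ for r < 1 — suppression can only depress the
linear signal.

Noise is multiplicative Gaussian on every peak intensity (relative sd,
default 0.01), truncated at zero — the simplest stand-in for
heteroscedastic counting noise; fragment current is split over 8
channels by a symmetric Dirichlet draw, which is immaterial to SY (only
the precursor/TIC split matters). No isotope envelopes, adducts or m/z
realism are attempted: the m/z axis is a label. One integer seed drives
everything, with per-sample sub-streams derived deterministically, so
equal seeds give bit-identical datasets.

## The IR branch

Raw spectra are simulated on the 675–4000 cm⁻¹ range at 1725 points:
Gaussian bands shared by both isomers (amide A/I/II, C–H stretch,
fingerprint), one linear-specific band at 2105 cm⁻¹ (width 18 cm⁻¹)
whose amplitude scales linearly with x — the unresolved alkyne + azide
stretches — plus a smooth random baseline (order-3 polynomial with
N(0, 0.05) coefficients per raw spectrum, emulating scattering drift)
and white noise (sd 0.02 absorbance). Each replicate is the exact
arithmetic mean of 100 raw spectra, mirroring a mapping acquisition that
averages one spectrum per grid point; the default design is 11 ratio
levels × 3 replicates = 33 averaged spectra, a 33 × 1725 matrix.

Preprocessing order is **average → normalise to mean absorbance → AsLS →
calibrate**. The ordering of normalisation and baseline correction was
genuinely open; normalising first was chosen so that the baseline
penalty λ acts on a common intensity scale across samples, and the order
is configurable at the function level (the steps compose freely).

**AsLS** estimates the baseline z minimising
$\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2$ with weights
re-set each iteration to p above the baseline and 1 − p below. The
penalty uses second-order differences (the standard Whittaker choice);
iteration stops when the largest weight change falls below $10^{-6}$ or
after 50 iterations, and the linear systems are solved sparsely. Defaults
p = 0.001, λ = 10⁴. `tune_asls()` scores candidate (p, λ) pairs by the
cross-validated error of a PLS model on the corrected spectra, after
flagging candidates whose corrected spectra dip below −2% of the maximum
corrected intensity — the quantitative version of discarding corrections
"with negative parts"; ties and ordering are made deterministic by
sorting candidates before the argmin.

**Quantification** is univariate — trapezoidal band area over
2040–2170 cm⁻¹ with linearly interpolated window endpoints, plain window
integration without local baseline anchoring (an absorbance-maximum mode
exists as an alternative response) — or multivariate: mean-centred PLS1
(NIPALS) on the full corrected matrix. Cross-validation is
contiguous-block with one block per concentration level (the replicate
triplets, 11 blocks of 3 at the default design), which prevents
replicate leakage. The latent-variable count minimises RMSECV, with ties
resolved toward fewer components (numerical ties within a $10^{-8}$
relative band count as ties, so noiseless data selects the minimal
rank). At full rank PLS1 reproduces OLS, which the tests use as an
oracle; rank deficits cap the component count with a warning.

## Figures of merit

Fit errors are predicted − reference per calibration standard;
percentage errors are undefined at reference 0 and reported as NA, never
as a division. RMSEC uses divisor n — the number of standards, all
replicates counted (n = 18 for the ER-MS design, 33 for IR) — not a
degrees-of-freedom-corrected divisor. Detection limits: univariate
$LD = 3.3\, s_e / |b_1|$ (3.3 for α = β = 0.05) and multivariate
$LD = 3.3 \cdot RMSEC$. For the ER-MS CLS model both routes are reported
side by side (`lod` and `lod_alt`), because the two rules genuinely
differ there and neither is canonically "the" CLS detection limit.
Intermediate precision is the degrees-of-freedom-weighted pooled
replicate variance, reported as a standard deviation; the pooling
convention (Bessel-corrected per group) is a documented choice where
"pooled variance" alone underdetermines it. The comparison report
carries one row per (technique, model) with linearity interval — (0, 0.3)
for ER-MS models, (0, 1) for IR — R², RMSEC, RMSECV where available,
intermediate precision, LD and n.

## Problem sizes used by the tests

The test suite validates the statistical claims at these sizes, chosen
as the smallest that make the checks stable: 200 simulated batches for
the slope-recovery and model-comparison checks (the mean fitted CLS
slope recovers the generator's low-range response factor within 5%;
whole-curve CLS achieves mean RMSEC at or below the single-voltage
model's, the expected direction since CLS averages noise over 13
voltages); 100 seeded mixtures for the CLS-vs-grid-scan oracle; single
full-size datasets for the structural checks (18 standards, 33 × 1725).
Unit tests use reduced grids (400-point spectra, 5–10 raw spectra per
replicate) for speed; nothing in the methods depends on grid size.

## What the synthetic data does and does not establish

The generator reproduces the *structure* the analysis relies on —
sigmoid ordering, convex mixing with suppression, two-regime
calibration, a ratio-proportional marker band under drift and noise,
replicate averaging — so passing tests establish that the estimators
recover known truth under that structure, that closed forms match
brute-force oracles, and that the pipeline is deterministic and
complete. They do not establish instrument-level performance: real
electrospray suppression varies with matrix and day, real IR baselines
are not polynomial, detector noise is correlated, and the reported
figures of merit on synthetic data reflect the generator's default noise
levels, not any laboratory's. Neither platform's noise magnitude is
documented in the source material, so the defaults are justified only by
qualitative resemblance of the simulated curves and spectra to their
experimental counterparts. Known limitations, by design: no vendor
formats, no time-domain spectrum combining, no internal-standard
correction, no estimated breakpoint, no scatter-correction alternatives
(MSC/SNV), no variable selection, no spatial/hyperspectral logic beyond
the averaging contract.
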