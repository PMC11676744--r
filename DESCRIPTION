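Package: cyclopure
Title: Purity Assessment of Click-Cyclised Peptides by Energy-Resolved MS
    and Mid-Infrared Chemometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the molar ratio of a linear peptide in mixtures with
    its isomeric Huisgen-cyclised product using two complementary platforms.
    The energy-resolved tandem mass spectrometry branch computes Survival
    Yield breakdown curves from centroided peak lists, fits Boltzmann
    sigmoids, and calibrates via a univariate delta-SY response at a fixed
    excitation voltage or via classical least squares unmixing of whole
    curves, including segmented and quadratic alternatives for the
    ion-suppression regime change. The mid-infrared branch preprocesses
    absorbance spectra (mean normalisation, asymmetric least squares
    baseline correction) and calibrates via the alkyne/azide band area or
    partial least squares with contiguous-block cross-validation. A common
    figures-of-merit engine reports RMSEC, RMSECV, detection limits and
    pooled intermediate precision, and a seeded synthetic-data generator
    reproduces the statistical structure of both platforms for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
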