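Package: thquant
Title: Targeted LC-MS Quantification of Thyroid Hormones and Polar
    Metabolites in Small-Volume Biofluids
Version: 0.1.0
Authors@R: person("Pipeline", "Maintainers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested re-implementation of a targeted liquid
    chromatography-mass spectrometry (LC-MS) processing chain for
    quantifying thyroid hormones (T3, T4) and ~200 polar metabolites in
    small-volume biofluids such as cerebrospinal fluid.  Provides
    monoisotopic mass and adduct m/z calculation from molecular formulas,
    a minimal centroided-mzML reader/writer, extracted ion chromatograms
    at ppm tolerance with retention-time-windowed trapezoidal peak
    integration, stable-isotope-dilution internal-standard normalization,
    pooled-QC filtering on coefficient of variation and dilution
    linearity, blank + 3 sigma limit-of-detection calibration, log/Pareto
    scaling with PCA and group statistics, and a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
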