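Package: mirwhey
Title: Chemometric Calibration of Mid-Infrared Milk Spectra for Whey
    Protein Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end chemometric workflow for quantifying the whey
    proteins beta-lactoglobulin and alpha-lactalbumin in milk from
    mid-infrared (MIR) absorbance spectra. Provides Hotelling T2 and
    Q-residual outlier screening on a NIPALS partial least squares
    decomposition, an automated ordered search over spectral
    preprocessing chains (normalization, scatter correction,
    Savitzky-Golay filtering), Kennard-Stone and random sample
    partitioning with replicate-aware cross-validation, two-stage
    wavenumber selection (interval PLS followed by a genetic algorithm
    over binned wavenumbers), and tuned PLS, support vector, ridge and
    linear regression calibration models. A synthetic MIR milk-spectra
    generator with known ground truth makes every stage testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
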