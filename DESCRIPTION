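Package: psmRescore
Title: Spectral-Prediction-Informed Rescoring of Peptide-Spectrum Matches
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A self-contained toolkit for rescoring peptide-spectrum matches
    (PSMs) from database search engines using features derived from predicted
    MS2 spectra and retention times. Computes spectral angle, ion-series
    coverage, fragment m/z error, retention-time error, adjacent-residue-swap
    sensitivity ("delta") and MHC binding-rank features; rescoring is performed
    with a cross-validated semi-supervised linear discriminant and target-decoy
    q-values, or exported as a Percolator pin file. Includes collision-energy
    calibration against a spectral predictor, construction of ground-truth
    benchmark databases with precision-recall evaluation, and a deterministic
    toy spectral predictor plus synthetic dataset generator so the whole
    pipeline is testable without external predictors or raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    glmnet,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
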