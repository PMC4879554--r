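Package: ramanclass
Title: Chemometric Classification of Raman Spectra by PC-LDA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying Raman microspectra of live cells and tissues:
    Savitzky-Golay derivative preprocessing, region interpolation and vector
    normalization; principal component analysis with significance-based factor
    selection feeding linear discriminant analysis (PC-LDA); leave-one-out
    cross-validation and frozen-model test prediction with confusion matrices
    and classification efficiencies; group mean and difference spectra with
    biochemical band annotation; single-hit clonogenic survival (D0) and
    delta-delta-Ct fold-change helpers; and a Lorentzian-band spectrum
    simulator for end-to-end validation without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
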