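Package: sersdecomp
Title: Shift-Tolerant Spectral Decomposition and Cohort Statistics for
    Serum SERS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for attributing bands of surface-enhanced Raman
    (SERS) spectra of human serum to their molecular origins: modified
    polynomial (modpoly) baseline subtraction, vector normalization,
    MAD/SuperSmoother band detection, non-negative spectral decomposition
    with sub-pixel component shifts and bootstrap confidence intervals on
    the figures of merit, band-intensity Spearman correlation against
    anchor bands, and centered unscaled principal component analysis.
    Includes a synthetic serum-spectrum generator (pseudo-Voigt component
    libraries, donor cohorts, spiking and isotopologue scenarios) so the
    whole chain can be exercised and validated without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    boot,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
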