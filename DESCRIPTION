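Package: wirespec
Title: Chemometric Analysis of SERS Line Scans Along Single Nanowire Probes
Version: 0.1.0
Authors@R:
    person("Wirespec", "Developers", email = "wirespec@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing surface-enhanced Raman scattering (SERS)
    spectra collected at micrometre steps along a single silver-nanowire
    probe inserted into 2D (monolayer) and 3D (spheroid) cell-culture
    models. Provides spectral containers with CSV and JCAMP-DX I/O, a
    synthetic line-scan generator with ground-truth region labels,
    SERS quality metrics (band area, relative standard deviation,
    enhancement factor), PCA-based culture-model discrimination with
    confidence ellipses and a KNN validation score, and a Random-Forest
    guided K-means++ procedure that localises protein-rich versus
    nucleic-acid-rich regions along the wire, including silhouette-based
    cluster-count selection and per-feature importance from a compiled
    random-forest classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    MASS,
    withr
Config/testthat/edition: 3
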