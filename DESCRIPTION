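Package: specphenonet
Title: Identification-Free Phenotype Classification of Tandem Mass Spectrometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classifies cancer phenotypes (control, ovarian, prostate, kidney)
    directly from raw tandem mass spectrometry peak lists in Mascot Generic
    Format, bypassing peptide and metabolite identification. Provides mgf
    reading and writing with a labeled dataset catalog and stratified splits;
    noise-reduction preprocessing (feature extraction on a retention-time
    grid, ppm-scale m/z quantization, rare-feature filtering, min-max scaling,
    elliptic-envelope outlier removal); an edge-extraction augmentation scheme
    for small cohorts; rendering of spectra into retention-time by m/z image
    sequences and volumes; a four-channel one-dimensional residual
    convolutional network and a three-dimensional convolutional network built
    on an internal neural-network engine with Adam training; evaluation with
    confusion matrices and inter-phenotype distance matrices; and a synthetic
    cohort generator with planted class markers for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    MASS,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
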