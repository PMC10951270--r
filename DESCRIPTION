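Package: glycospectra
Title: Prediction of Intact Glycopeptide Fragment Spectra with Tree
    Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts HCD fragment ion intensities of intact N-glycopeptides
    from the peptide sequence and the glycan tree topology. A bidirectional
    LSTM encodes the peptide, a child-sum tree LSTM encodes the glycan, and
    attention over an explicit fragmentation graph of glycosidic cleavages
    produces Y- and B-ion intensities alongside peptide b/y ions. Includes
    theoretical fragment enumeration, spectrum annotation and consensus
    building, multi-task training with spectral-angle losses and dynamic
    weight averaging, rescoring of glycan structural isomers against
    predicted spectra, predicted spectral-library generation for DIA, and a
    ground-truth fragmentation simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    withr,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
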