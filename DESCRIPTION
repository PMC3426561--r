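Package: vironet
Title: Neural Network Ensembles for Detecting Viral Structural Proteins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects viral and phage structural proteins (capsid, tail,
    portal, baseplate, and related virion components) from translated ORF
    sequences. Protein sequences are encoded as amino-acid percent
    composition, optionally augmented with a Henderson-Hasselbalch
    isoelectric-point estimate, and classified by ensembles of
    hyperbolic-tangent multilayer perceptrons trained with the
    Levenberg-Marquardt algorithm under validation-based early stopping.
    Includes keyword-based curation of annotated sequence sets, K-fold
    cross-validation with architecture and split-ratio grid search,
    top-N voting ensembles, sensitivity/specificity evaluation with
    subsampling confidence bands, and a synthetic sequence generator for
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
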