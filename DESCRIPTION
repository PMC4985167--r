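Package: profam
Title: Protein Functional Family Classification from Sequence-Derived Descriptors
Version: 0.1.0
Authors@R:
    person("profam", "developers", email = "profam@example.org", role = c("aut", "cre"))
Description: Predicts protein functional-family membership from sequence alone,
    without alignment or similarity search. Protein sequences are encoded as
    structural and physicochemical descriptors (amino-acid composition,
    composition/transition/distribution encodings over three-class property
    groupings, Moreau-Broto autocorrelation, and pseudo-amino-acid
    composition), and per-family binary classifiers are trained with one of
    three backends: a Gaussian-kernel soft-margin support vector machine with
    Platt posterior-probability calibration, k-nearest-neighbour with
    Euclidean distance, or a probabilistic neural network (Parzen-window
    density classifier). Includes the staged dataset-construction protocol
    (grouped positive splitting, domain-family based negative sampling,
    cross-partition deduplication, tune/retrain/evaluate/finalize),
    sensitivity/specificity/precision evaluation for imbalanced classes, a
    synthetic-family generator for download-free benchmarking, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
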