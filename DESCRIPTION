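Package: prip
Title: RNA-Binding Interface Prediction from Protein Sequence Semantics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Residue-level prediction of protein-RNA binding interfaces from
    primary sequence alone. Protein chains are divided into fixed-length,
    X-padded windows centred on each residue; residues are embedded as words
    with a deterministic single-worker CBOW/skip-gram negative-sampling
    trainer; windows are featurized by concatenating the embeddings; and a
    from-scratch regularized second-order gradient-boosted tree ensemble
    classifies each centre residue. Includes interface labelling from
    protein-RNA complex coordinates by the 5 Angstrom rule, composition
    baseline encoders (AAC, DPC, CKSAAPGP), confusion-matrix metrics with
    ROC/AUROC and stratified cross-validation, a window-length scan,
    semantic-specificity testing against shuffled-corpus null embeddings,
    positional residue enrichment, a synthetic benchmark generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    withr,
    Biostrings,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    pROC
Config/testthat/edition: 3
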