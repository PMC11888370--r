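Package: delcube
Title: Design, Decoding, and Enrichment Analysis for DNA-Encoded Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An informatics toolkit for DNA-encoded library (DEL) screening:
    error-correcting quaternary (GF(4)) Hamming barcode design, combinatorial
    library enumeration from building-block sets and a reaction scheme,
    decoding of NGS selection reads into UMI-corrected per-compound count
    ("cube") tables via two-stage semi-global alignment with tag error
    correction, enrichment and mono/disynthon analysis, and a selection
    simulator with full ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    yaml,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr
Config/testthat/edition: 3
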