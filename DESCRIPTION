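Package: ibdancestry
Title: Reference-Based Global Ancestry Estimation from Long Haplotype Matches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Estimates the global ancestry composition of phased query
    haplotypes against a population-labelled reference panel. Long exact
    haplotype matches (identity-by-descent proxies) are called with a
    positional Burrows-Wheeler transform long-match engine, converted into
    per-site ancestry dosages through a population-by-site score matrix, and
    aggregated into per-individual ancestry proportions. Includes a
    windowed-resampling procedure that refines heterogeneous reference panels
    into more homogeneous synthetic haplotypes, a mosaic admixture simulator
    with known local-ancestry truth for validation, accuracy metrics (RMSE
    and Kullback-Leibler divergence), and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    vcfR,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
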