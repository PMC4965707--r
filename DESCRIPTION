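Package: omsweep
Title: De Novo Assembly of Optical Restriction Maps with Memoized Parameter Sweeps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for de novo assembly of single-molecule restriction maps
    (Rmaps) from nanochannel optical-mapping experiments. Reads and writes the
    BNX and CMAP text formats, simulates noisy labeled molecules from a
    reference under an explicit error model (false-positive labels,
    false-negative labels, interval sizing noise, stretch), scores oriented
    pairwise overlaps with a dynamic-programming aligner and assigns
    permutation-based alignment p-values, assembles molecules by
    overlap-layout-consensus, and evaluates assemblies for contiguity,
    internal consistency and reference accuracy. A parameter-sweep engine
    runs grids of assembly parameter combinations while detecting and reusing
    compatible intermediate results, so a full grid costs only the distinct
    computations it actually requires.
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
    yaml,
    stats,
    utils,
    optparse,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
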