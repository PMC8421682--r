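Package: comodule
Title: Common Module Discovery in Multilayer Networks by Joint
    Non-Negative Matrix Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects "common modules" -- vertex sets that are densely
    interconnected in every layer of a multilayer network simultaneously --
    by jointly factorizing the layer adjacency matrices with non-negative
    matrix (tri-)factorization under multiplicative updates. Includes the
    multilayer modularity-density quality model based on the geometric mean
    of per-layer connectivity, construction of co-expression and
    co-methylation layers from gene profile matrices via Pearson correlation
    with a PCIT trio filter, an instability criterion for choosing the
    number of modules across random restarts, a planted-partition
    (Girvan-Newman style) multilayer benchmark generator with controllable
    noise, and normalized mutual information for evaluating partitions
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    tibble,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
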