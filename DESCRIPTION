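Package: wormcycle
Title: Boolean Threshold-Network Dynamics of the C. elegans Early Embryonic Cell Cycle
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synchronous threshold Boolean network toolkit built around the
    eight-regulator signed network controlling the S/M oscillations of early
    Caenorhabditis elegans embryonic cell cycles. Provides exact attractor and
    basin-of-attraction enumeration over the full state space, cell-cycle
    trajectory simulation with phase labelling, degree- and sign-matched random
    network null ensembles, single-edge perturbation robustness analysis
    (delete/add/switch with relative basin-size changes), and in-silico gene
    knockdown mimicking RNAi. Networks are built from tidy edge-list data
    frames; results are returned as tibbles with broom-style tidy() and
    glance() methods and ggplot2 visualisations. Includes edge-list TSV, SIF,
    GraphML and state-transition-graph exports plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
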