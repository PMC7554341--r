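Package: logimodel
Title: Building, Propagation Analysis and Specification-Based Verification of Logical Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing and analysing Boolean and multivalued logical
    models of cellular networks. Models are read from 'bnet'-style rule tables or a
    native JSON dialect with multivalued components. The package computes value
    propagation (percolation) of clamped components through the logical rules,
    differential comparisons of alternative perturbations with annotated graph
    export, sub-model extraction around a selected component set, stable states and
    minimal trap spaces with exhaustive small-model oracles, and runs YAML
    specification suites that encode expected component activities as automated
    model tests, in the spirit of unit testing for dynamical models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
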