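Package: startstop
Title: Design and Simulation of Functionally Scarless Golden-Gate DNA Assembly
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An in silico workbench for hierarchical, functionally scarless
    Golden-Gate-type DNA assembly ("start-stop" assembly), in which the start
    (ATG) and stop (TAA) codons themselves serve as the 3 bp fusion sites at
    coding-sequence boundaries. Provides a DNA sequence and type IIS enzyme
    model with complete-digest simulation into cohesive-ended fragments;
    the fusion-site registry and overhang fidelity audit; Level 0 part typing,
    validation and domestication (prefix/suffix primer tails); a registry and
    synthetic-sequence generator for the fifteen core storage and assembly
    vectors; one-pot restriction-ligation simulation with enumeration and
    classification of circular products; a hierarchical assembly planner
    (up to 15 expression units in monocistronic, operon or hybrid
    configurations, with Z-vector substitution and bench recipes); and
    design-space arithmetic, coverage estimation and seeded sampling for
    combinatorial expression libraries.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
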