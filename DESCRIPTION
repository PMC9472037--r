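Package: tripcausal
Title: Causal Analysis of Driving Behavior and Momentary Well-Being
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Workflow for causal analysis of observational trip-level
    driving data: structure learning of a causal directed acyclic graph by
    continuous optimization with an acyclicity constraint and a-priori
    forbidden edges, backdoor-criterion identification of adjustment sets,
    adjusted-regression estimation of standardized causal effects, and a
    random-confounder robustness test.  Includes a linear-Gaussian
    structural equation model simulator for trip tables with the study's
    four variable categories (emotions, driving behavior, trip-dependent
    and predetermined factors), a per-second driving-signal generator, and
    extractors for the derived driving-behavior features (steering and
    braking ratios, sudden-event rate, flow).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
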