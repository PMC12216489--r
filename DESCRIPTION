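Package: dmscreen
Title: Deep Mutational Scanning Selection Screens: Simulation, Read
    Processing and Site Scoring
Version: 0.1.0
Authors@R:
    person("DMS", "Screen Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing deep mutational scanning (DMS) selection
    screens of bacterial CRISPR adaptation genes (cas1/cas2/csn2-like),
    from barcoded-subamplicon sequencing reads to per-site amino-acid
    preferences, wild-type-relative differential selection, Shannon
    entropy, and a composite gain-of-function site score.  Includes a
    fully seeded synthetic-data generator (codon-mutant libraries with
    Poisson mutation loads, selection with planted per-substitution
    fitness effects, barcoded subamplicon reads with substitution
    errors, plating, phage-survival and competition count data) so every
    stage of the pipeline can be validated against known ground truth,
    plus the plate-count statistics used to validate candidate variants
    (selective/total CFU acquisition rates, Welch t-tests, phage-immunity
    folds, growth-competition analysis).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
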