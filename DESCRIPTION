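Package: nicsgrade
Title: Noninvasive Chromosome Screening Simulation, Copy-Number Calling
    and Euploidy Grading
Version: 0.1.0
Authors@R: person("NICS", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Simulates shallow whole-genome sequencing read counts from
    spent embryo culture medium, calls copy-number variants with circular
    binary segmentation, extracts the eleven-feature mosaicism-aware
    representation used by noninvasive chromosome screening (NICS) grading,
    trains a random-forest euploidy classifier that maps embryos to A/B/C
    transfer grades, and computes the stratified contingency-table and
    logistic-regression statistics used to compare clinical outcomes
    between screening strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
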