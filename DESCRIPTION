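Package: cpnmci
Title: Counterpropagation Networks for Mild Cognitive Impairment Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Clinical decision support for mild cognitive impairment (MCI)
    screening from five routinely collected variables (age, years of
    education, MMSE, FAQ and GDS). Implements a Counterpropagation Network --
    a Kohonen self-organizing map with square or hexagonal lattice and planar
    or toroidal connectivity, cascaded into a Grossberg outstar readout --
    together with wrapper feature selection (exhaustive enumeration and
    backward elimination), a diagnostic-accuracy suite (ROC threshold sweep,
    convex-hull AUC, balanced threshold selection, clinical utility indices),
    single-test cut-off evaluation, and a synthetic cohort generator that
    emulates the group-wise structure of an ADNI-derived control/MCI sample.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
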