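Package: metanash
Title: Plasma Metabolomics Pipeline for NASH Discrimination
Version: 0.1.0
Authors@R:
    person("Metanash", "Developers", email = "metanash@example.org",
           role = c("aut", "cre"))
Description: A reusable analysis pipeline for targeted plasma metabolomics
    of nonalcoholic fatty liver disease (NAFLD): seeded synthetic cohort
    generation calibrated to published group statistics, nonparametric
    univariate screening with Benjamini-Hochberg false discovery rate
    control, random-forest feature halving with cross-validated tuning,
    single-feature multinomial logistic probability curves with
    "green window" extraction, decision-tree feature reduction, and the
    MetaNASH weighted log-product diagnostic score with Youden-style
    cutoff selection and comparator indices (GSG, glutamate/glutamine,
    FIB-4, NFS, C3).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
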