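Package: clonotrace
Title: BCR Repertoire Clonality, Diversity and Survival Analysis for
    CLL Mouse Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of B-cell receptor (BCR) repertoires from murine
    chronic lymphocytic leukemia (CLL) cohorts such as the Eu-TCL1
    transgenic model. Reads clone tables in AIRR Rearrangement or
    MiXCR-like TSV dialects, aggregates clonotypes by CDR3 amino-acid
    identity, calibrates a CLL-clone threshold against wild-type
    repertoires, classifies clonality (monoclonal, biclonal,
    oligoclonal), computes the normalized Herfindahl-Hirschman diversity
    index and its age trend, summarizes junction N-insertions and
    clone-fraction-weighted Levenshtein distances of CDR3 sequences per
    IGHV subgroup, and provides the cohort statistics layer (Wilcoxon
    rank-sum, Fisher's exact test with conditional-MLE odds ratio,
    Kaplan-Meier estimation, pairwise log-rank with Benjamini-Hochberg
    adjustment, Mantel-Haenszel hazard ratios). A synthetic-cohort
    generator reproduces the statistical structure of such cohorts for
    testing and power exploration without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
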