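Package: famanc
Title: Pedigree-Aware Correction of Local Ancestry Inference Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Improves per-marker diploid local ancestry calls made in two-way
    admixed pedigrees by upstream tools that assume individuals are unrelated.
    Detects inference errors from Mendelian inconsistencies, improbably short
    double-crossover reversions and low-confidence calls, estimates the
    allelic error rate from observed Mendelian errors in nuclear families,
    and corrects flagged loci by maximum a-posteriori selection over
    Mendelian-consistent configurations under a Markov model of ancestry
    switches along the genetic map. Includes a gene-dropping simulator of
    ancestry tracks in pedigrees so the whole pipeline can be exercised on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
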