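Package: magbias
Title: Completeness Bias in Metagenome-Assembled Genome Functional Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and corrects the bias that incomplete
    metagenome-assembled genomes (MAGs) introduce into inferred metabolic
    function fullness. Provides simulators for synthetic module catalogs and
    genomes (including mechanistic incompleteness by random contig dropout and
    single-copy core-gene completeness estimation), distillation of gene
    annotations into KEGG-style module fullness, per-module weighted binomial
    generalised linear models of fullness on completeness by phylum, a
    mixed-effects meta-analysis of the fullness-completeness slopes with
    parametric-bootstrap confidence intervals, a model-based correction of
    functional profiles of incomplete genomes, and principal coordinates
    analysis of functional profiles to visualise and validate the correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
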