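Package: apexbiome
Title: Microbiome Cohort Analysis for Root-Apex 16S Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Downstream analysis of 16S rRNA OTU count tables from
    root-apex (apical periodontitis) cohort studies: rarefaction and
    taxonomic aggregation, alpha-diversity estimation (observed OTUs,
    Chao1, Shannon, Gini-Simpson) with rank-based group comparisons,
    multi-criterion differential abundance (Wilcoxon tests, Storey
    q-values, fold change and an upper-quartile abundance floor),
    pairwise sample-overlap decompositions, Pearson co-occurrence
    networks with k-core structure, lesion-size subtype clustering with
    concordance testing, and a calibrated synthetic cohort generator
    with planted effects for end-to-end validation. Results are tidy
    tibbles designed for piped workflows, with ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
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
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
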