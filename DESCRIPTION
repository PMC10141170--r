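Package: glycomod
Title: Glycan-Driven Modulation of Gut Microbial Communities from 16S Amplicon Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of prebiotic- and medicinal-herb-driven restructuring of in
    vitro gut microbial communities from 16S rRNA amplicon data. Implements
    multi-taxonomy assignment of amplicon sequence variants from alignment hit
    tables (the M-(1-M)/4 identity-window rule with "/"-joined multi-names),
    hierarchical 16S copy-number renormalization of abundances, genome-content
    community phenotype indices (CPI) for fermentation products, vitamins and
    CAZyme (GH/PL) families from binary phenotype matrices, five-fold modulation
    scoring against control cultures, exact small-sample Mann-Whitney inference
    by full enumeration, and pairwise f-score overlap analysis of
    treatment-responsive taxa. A synthetic-data generator with planted ground
    truth emulates every input format so the full pipeline is testable without
    external databases.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
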