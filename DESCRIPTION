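Package: mipnr
Title: Calling Microbial Partners from Bait-Capture Metagenomic Count Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of bait-capture ("MiPner") soil microbiome
    experiments from per-sample taxonomic read-count tables. Reads Kraken-style
    classifier reports and Bracken abundance files, merges them into a combined
    count table, removes archaeal, viral and human reads, computes genus- and
    species-level relative abundances with bait masking and renormalization,
    and classifies taxa as putative microbial partners of the bait, stick-binder
    false positives, or non-candidates using top-N ranking, a tiered
    presence/absence rule against the binder control, and fold-enrichment
    against the source community. Includes alpha-diversity summaries (richness,
    Simpson's index) with one-way ANOVA and Tukey HSD comparisons, shared-taxa
    set intersections, and a Dirichlet-multinomial synthetic-community generator
    with planted ground truth for end-to-end recovery testing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
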