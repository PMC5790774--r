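Package: thprof
Title: Tissue Expression Profiling of T Helper Subset Regulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Database-mining style analysis of CD4+ T helper (Th) subset
    regulator expression across tissues. Implements beta-actin-normalized
    arbitrary units, the housekeeping mean-plus-two-SD significance
    threshold, the one-transcript-per-million no-expression rule, and
    trichotomous expression calling; aggregates per-gene calls into
    Th-subset summaries, tissue-pyramid rankings, dominance reports and
    immune-privilege flags; classifies case-versus-control regulation with
    the signed fold-change convention and tallies regulation over gene sets
    such as the MHC class II panel; partitions regulated sets into exact
    Venn regions; and ships a seeded synthetic-data generator with planted
    truth so every stage is testable without any database access.
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
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
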