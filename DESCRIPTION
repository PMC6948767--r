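Package: concoex
Title: Consensus Coexpression Analysis Across Expression Compendia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for consensus gene coexpression analysis across multiple
    bulk expression datasets: an ANOVA-based dataset consistency filter for a
    query gene, per-dataset top-K correlation profile-neighbor ranking,
    cross-dataset consensus counting, mutual-rank validation on a held-out
    compendium, and Fisher's exact term overrepresentation with
    Benjamini-Hochberg FDR control. Includes a synthetic expression compendium
    generator with a planted co-regulated module for end-to-end validation,
    and helpers for common immunology assay arithmetic (europium-release
    specific lysis, comparative delta-delta-Ct quantification, NK cell count
    summaries, Welch two-group tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    withr,
    ggplot2,
    jsonlite,
    generics,
    fgsea,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
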