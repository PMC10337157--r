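Package: agesig
Title: Multi-Tissue Multi-Time-Point Aging Gene-Expression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies age-related genes from bulk RNA-seq time courses and
    characterises how they change over the lifespan. Raw counts are normalised
    to log2 counts-per-million, genes passing fold-change and Bonferroni gates
    versus a reference age are fitted with null, linear and four-parameter
    logistic trajectory models and classified by BIC into linear or
    early/mid/late-logistic, up or down classes. Downstream stages test
    pathway over-representation per trajectory class with Fisher's exact test
    and a cross-tissue retention filter, test cross-species direction
    concordance of orthologous age-related genes with an upper-tail
    hypergeometric probability, and associate transcription factors with
    enriched pathway systems by pre-ranked gene-set enrichment on
    Spearman-ranked regulator-target interactions. A synthetic-data generator
    with planted trajectories, gene sets, ortholog maps and regulator networks
    makes every stage testable without external data.
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
    Matrix,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    fgsea,
    limma,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
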