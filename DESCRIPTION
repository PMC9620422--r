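Package: keydriver
Title: Key Driver Analysis and Enrichment for Directed Gene Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream transcriptomic analysis built around key driver
    analysis (KDA) on directed gene regulatory networks. Computes h-layer
    neighborhood (HLN) statistics, selects candidate driver genes above the
    mean-plus-one-standard-deviation HLN cutoff, classifies them into global
    and local drivers via the root-node rule, and applies the
    two-standard-deviation out-degree rule for global driver genes. Also
    provides differential-expression filtering (|log2 fold change| and
    Benjamini-Hochberg Q-value thresholds), hypergeometric
    over-representation analysis of gene-set collections, a permutation-based
    gene set enrichment analysis (running-sum enrichment score, normalized
    enrichment score, permutation significance), seeded synthetic-data
    generators that plant known drivers, effects and enriched terms for
    end-to-end verification, and a deterministic pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
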