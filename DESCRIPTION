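Package: metabotyper
Title: Metabotype Classification and Metagenome Association for
    Microbiome-Mediated Drug Reactivation
Version: 0.1.0
Authors@R:
    person("Metabotyper", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to link ex vivo SN-38G to SN-38 turnover phenotypes
    ("metabotypes") of human gut communities to shotgun-metagenome features.
    Implements internal-standard calibrated LC-MS/MS quantitation and percent
    formation, largest-gap metabotype classification, Welch's t-test
    differential feature abundance with Storey q-values and a
    ratio-of-proportions effect-size filter, Simpson's equitability evenness
    contrasts, odds-ratio enrichment classification of enzymes, and
    community metabolic network construction with betweenness-centrality
    tiers, Wilcoxon, Spearman and hypergeometric tier tests. A seeded
    synthetic-data generator emulates every pipeline input so the full
    analysis runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
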