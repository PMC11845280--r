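Package: netrewire
Title: Condition-Specific Protein Interaction Networks and Differential
    Rewiring Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Contextualizes a reference protein-protein interaction network
    (PPIN) per sample by mapping interactions onto a domain-domain
    interaction network (DDIN) and pruning to interactions supported by the
    major (most abundant) transcript of each protein, following expression
    data at gene or transcript level. Detects statistically significant
    rewired interactions between two groups of condition-specific networks
    with a one-tailed binomial test on pairwise rewiring counts and
    Benjamini-Hochberg false discovery rate control, and attributes the
    significant alterations to a minimal set of transcriptomic changes
    (expression gains/losses and isoform switches) via a greedy weighted
    set cover. Includes seeded generators for fully synthetic benchmark
    scenarios with plantable ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
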