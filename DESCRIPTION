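Package: coocnet
Title: Co-Occurrence Network Analysis of Size-Fractionated Marine Bacterial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds correlation-based co-occurrence networks from
    size-fractionated 16S OTU count tables together with environmental and
    phytoplankton covariates: prevalence/abundance filtering, Spearman rank
    correlation with Benjamini-Hochberg false-discovery control, monthly
    thresholded networks, Erdos-Renyi null ensembles and the small-world
    coefficient, Louvain modules, within-module degree (Z) and participation
    coefficient (C) node roles, module depth-preference classification, and
    recurrence networks of correlations repeated across months. Includes
    alpha-diversity summaries (Shannon, bias-corrected Chao1, Simpson
    evenness) and a synthetic-data generator that emulates a depth-stratified
    coastal sampling grid with planted correlation modules, hubs and
    environmental drivers so the whole pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
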