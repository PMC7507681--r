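Package: resistnet
Title: Two-Timepoint Somatic Mutation and Interaction-Network Analysis of
    Acquired Drug Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for contrasting tumor mutation catalogs sampled before and
    after acquired resistance to targeted therapy. Classifies somatic
    alterations as persisting, newly arisen, or lost between two sequencing
    timepoints and summarizes their variant allele frequency (VAF) structure;
    computes protein-protein interaction network topology statistics (degree,
    local clustering coefficient, average neighbor degree, closeness) on the
    giant component and assesses mutated gene sets against a degree-matched
    random-resampling null model with empirical p-values; performs
    hypergeometric gene-set enrichment against the network background with
    false-discovery-rate control; implements ultra-deep panel post-processing
    (somatic candidate read-support filters, copy-number classification,
    discordant read-pair collection and breakpoint clustering, tumor
    mutational burden); and analyzes patient-derived xenograft drug screens
    (tumor volume, percent tumor growth inhibition, humane-endpoint flags).
    A synthetic-data module generates scale-free networks, two-timepoint
    catalogs with a binomial read-count model, planted-term annotation maps,
    and exponential tumor growth curves so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
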