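Package: todchron
Title: Trees of Protein Domains, Evolutionary Chronologies and Venn-Group
    Timelines from Proteome Censuses
Version: 0.1.0
Authors@R:
    person("Evolutionary Genomics", "Toolkit", email = "todchron@example.org",
           role = c("aut", "cre"))
Description: Tools for structural phylogenomics of protein domain families.
    Reads censuses of domain-family abundance across proteomes of Archaea,
    Bacteria, Eukarya and viruses, encodes them as linearly ordered multistate
    phylogenetic characters, infers trees of domains by Wagner maximum
    parsimony (Sankoff dynamic programming, heuristic search, bootstrap),
    roots them with hypothetical max/min-state ancestors (Lundberg
    optimization), derives node-distance chronologies calibrated to geological
    time, assigns Venn groups over the four supergroups and delimits
    evolutionary phases, computes proteome-occupancy (f-value) statistics with
    rank-sum comparisons, builds NeighborNet circular split networks from
    Venn incidence data, projects loop prototypes onto the domain chronology,
    and generates synthetic censuses with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
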