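Package: coreflow
Title: Bacterial Species Delimitation by Gene Flow on Core-Genome Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delimits bacterial species by gene flow from aligned core-genome
    concatenates. Computes average nucleotide identity (ANI) of core genes and
    single-linkage species clusters, infers homoplasic versus non-homoplasic
    alleles (the h/m ratio) by small parsimony on a neighbor-joining guide tree,
    detects truly clonal species with a forward-in-time clonal simulation null
    and with linkage-disequilibrium decay, quantifies between-species gene flow
    with the normalized h/m_norm statistic and a convergent-mutation null,
    scores introgressed 100-bp windows (the introgression score S_i), and models
    the availability of minimal efficient processing segments (MEPS) between
    diverged genomes. Ships a ground-truthed synthetic-data generator
    (clonal and gene-conversion populations, diverged candidates, injected
    introgression) used to validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
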