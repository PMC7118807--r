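Package: dmsearch
Title: Network-Assisted Dense Module Search for GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies disease-associated gene modules by superimposing
    gene-based genome-wide association scores onto a protein-protein
    interaction network. Implements greedy dense module search on a
    node-weighted network, discovery/evaluation selection of modules with
    consistent signals across two GWAS datasets, an edge-weighted variant
    driven by case/control differential co-expression with permutation
    significance, SNP-to-gene p-value aggregation, hypergeometric gene-set
    enrichment with redundancy reduction, and a synthetic-data generator
    with planted modules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
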