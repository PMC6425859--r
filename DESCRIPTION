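Package: OrthoCurator
Title: Tree-Based Curation of Hierarchical Ortholog Groups
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconciles graph-based ortholog groups with homolog-family
    labellings into a hierarchical catalog of fungal ortholog groups (FOGs)
    nested in homolog groups (HOGs), and curates the catalog against rooted
    gene trees: duplication nodes are inferred by the species-overlap rule,
    over-clustered groups are split at well-supported duplications, and
    under-clustered groups are merged when no organism carries a gene
    duplication. Additional proteins are rescued from parsed similarity and
    phylogenetic-placement tables with length and likelihood-weight-ratio
    filters, per-group consistency checks flag localization and length
    outliers, and the congruence of two ortholog databases is classified
    group by group. A birth-death gene-family simulator provides ground
    truth for every stage. Readers and writers cover TSV, JSON, orthoXML,
    Newick and FASTA.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    phangorn,
    jsonlite,
    xml2,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
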