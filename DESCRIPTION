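Package: mosmir
Title: Discovery, Quantification and Annotation of Mosquito microRNA Genes from Small RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis for microRNA (miRNA)
    gene discovery in mosquitoes. Reads from stage-specific libraries are
    adapter-trimmed, length-selected and collapsed into unique tags; tags are
    mapped to a reference genome allowing at most one mismatch; candidate
    precursor windows (100 nt of flank on each side) are folded with a
    built-in single-stem nearest-neighbour minimum-free-energy engine and
    judged against stem-loop criteria (mature in one arm, clean duplex,
    free energy below -20 kcal/mol, intergenic or intronic context) plus
    read-stack confirmation; accepted genes are classified by homology into
    conservation/lineage categories, quantified as counts per million with a
    15-read expression gate, clustered across developmental stages, and
    annotated with seed-weighted 3'UTR target predictions and Gene Ontology
    enrichment (Fisher's exact test, Benjamini-Hochberg FDR). A synthetic-data
    generator plants ground-truth hairpins so every stage is testable at desk
    scale, and the catalog of novel miRNAs reported for Aedes albopictus is
    packaged as a plain-text fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    rtracklayer,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
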