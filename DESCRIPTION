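Package: ceRNAnet
Title: Inference of lncRNA-miRNA-mRNA Competing Endogenous RNA Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies drought-deregulated lncRNA-miRNA-mRNA competing
    endogenous RNA (ceRNA) triplets from transcript sequences, a gene
    annotation and an expression matrix. Candidate lncRNAs are filtered by
    length and coding potential and assigned positional classes (intronic,
    antisense, intergenic); expression is normalised (RPKM/TPM) and
    differential expression called at conventional cutoffs; miRNA response
    elements are predicted with a plant-style complementarity penalty score;
    signed Pearson co-expression thresholds and a ceRNA score select
    triplets, which are assembled into a typed tripartite network with hub
    detection and Cytoscape-compatible export. A synthetic-data generator
    plants ceRNA triplets with known ground truth so that every stage of the
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
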