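Package: metago
Title: Gene Ontology Over-Representation Analysis for Metabolite Lists
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a metabolic Gene Ontology knowledgebase that links
    genes, transcripts, proteins, Enzyme Commission numbers, KEGG
    reactions and KEGG compounds from standard public source files (GO
    OBO, NCBI gene2go and gene2accession, Expasy enzyme.dat, KEGG REST
    link tables), and runs Gene Ontology term over-representation
    analysis on a list of KEGG compound identifiers using the upper-tail
    hypergeometric test with relevance filters and Benjamini-Hochberg
    false discovery rate control. Results can be exported as CSV tables,
    impact-plot tables, GO ontology networks and per-term metabolic
    reaction networks in Cytoscape SIF format with node-attribute files.
    Includes a deterministic generator of miniature source files so the
    full pipeline is testable offline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
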