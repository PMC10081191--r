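# metago

Gene Ontology over-representation analysis for metabolite lists.

Pathway enrichment for metabolomics depends heavily on which curated
pathway database is used as background: pathway definitions and
metabolite coverage differ between databases, and the same input list
can yield contradictory interpretations. Gene Ontology (GO) terms are a
standardized, much broader vocabulary of biological processes, but
classical GO enrichment tools accept genes and proteins, not
metabolites. `metago` closes that gap: it builds a **metabolic GO
knowledgebase** that chains genes → transcripts → proteins → Enzyme
Commission (EC) classes → KEGG reactions → KEGG compounds, restricted to
the metabolic-process sub-ontology (GO:0008152) of one taxon, and then
tests a list of KEGG compound identifiers for GO-term
over-representation.

It is intended for metabolomics researchers who have a list of
statistically significant metabolites (as KEGG C-numbers) and want a
process-level interpretation that is not limited to hand-drawn pathway
maps, plus Cytoscape-ready network exports for figures.

## The statistic

For each GO term with at least one linked compound, the p-value is the
upper tail of the hypergeometric distribution,

    p = P[X >= x],   X ~ Hypergeometric(y successes, a failures, b draws)

where

* `x` — overlap between the mapped input list and the term's compound set,
* `y` — number of compounds linked to the term,
* `a = N − y` — the rest of the background universe, with `N` the number
  of distinct compounds linked to any metabolic GO term in the
  knowledgebase,
* `b` — number of input compounds found in that universe.

In R terms this is `phyper(x - 1, y, a, b, lower.tail = FALSE)`.
Three relevance filters are applied before multiple-testing adjustment
(`x >= 3`, at least 3 genes annotated to the term, and `x > 5%` of `y`),
and the surviving p-values are adjusted with the Benjamini–Hochberg
step-up procedure; terms with q < 0.05 are reported as significant.

## Worked example

The package ships a synthetic knowledgebase that reproduces a classic
statistical frame: a 2,212-compound GO-linked universe, a nucleoside
salvage term (GO:0043174) with 61 linked compounds and 4 annotated
genes, and a 62-compound input list of which 13 fall in the term's set:

```r
library(metago)
kb     <- worked_example_kb()
report <- run_ora(kb, worked_example_input())
ora_table(report)[1, c("term_id", "term_name", "x", "y", "a", "b",
                       "gene_count", "p_value", "q_value")]
#>      term_id          term_name  x  y    a  b gene_count      p_value
#> 1 GO:0043174 nucleoside salvage 13 61 2151 62          4 4.218424e-09
#>        q_value
#> 1 4.218424e-09
```

Reading the row: 13 of the 62 mapped input compounds fall among the 61
compounds of nucleoside salvage; under random sampling from the
2,212-compound universe that overlap has probability 4.2e-09, far below
the q < 0.05 cutoff — the process is strongly over-represented.

A full offline pipeline on generated miniature sources:

```r
sources <- generate_mock_sources(fixture_spec(seed = 42), tempfile())
kb <- build_knowledgebase(sources)
kb
#> <metago knowledgebase> metago-kb-json/1 metago-1.0.0 tax:9606 root:GO:0008152
#>   go_terms_metabolic      6
#>   go_terms_with_gene      5
#>   go_terms_with_compound  3
#>   genes                   4
#>   transcripts             5
#>   proteins                5
#>   ec_numbers              3
#>   reactions               2
#>   compounds               6
#>   background_n            6

report <- run_ora(kb, c("C00002", "C00004", "C00006"),
                  min_overlap = 1, min_genes = 1, min_overlap_fraction = 0)
impact_table(report)                      # set size vs -log10(p)
net <- reaction_network(kb, report$results$term_id[1])
write_sif(net, "term_network.sif")        # open in Cytoscape
write_node_attributes(net, "term_network_nodes.tsv")
```

To build a real knowledgebase, download the public sources (GO
`go.obo`, NCBI `gene2go` and `gene2accession`, Expasy `enzyme.dat`,
KEGG REST `link/rn/ec` and `link/cpd/rn` tables, and a pre-fetched
EC→protein table) into one directory and run:

```sh
Rscript inst/cli/metago build-kb <source_dir> kb.json.gz
Rscript inst/cli/metago analyze kb.json.gz significant_compounds.txt results/
Rscript inst/cli/metago network kb.json.gz GO:0043174 results/ --detected significant_compounds.txt
Rscript inst/cli/metago query kb.json.gz C00385
```

`analyze` writes the result table (CSV and an Excel-compatible
tab-delimited copy), the impact table, and the GO ontology network of
significant terms in Cytoscape SIF format with a node-attribute file.
Exit codes are stable for scripting: 0 ok, 2 parse/build error, 3 no
input compound mapped, 4 unknown identifier.

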