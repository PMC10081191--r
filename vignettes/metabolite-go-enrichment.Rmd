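---
title: "Metabolite GO enrichment: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolite GO enrichment: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metago)
```

# The problem

A metabolomics experiment typically ends with a list of metabolites
that differ significantly between conditions. Interpreting that list
through pathway maps is fragile: different curated databases draw
different pathway boundaries and cover different metabolite sets, so
the enrichment result depends on the background database as much as on
the data. Gene Ontology (GO) biological-process terms offer a
standardized and much denser vocabulary, but GO annotations attach to
genes, not metabolites. `metago` bridges the two by building a
knowledgebase in which every metabolic GO term is linked to the KEGG
compounds its annotated genes can act on, through the chain

> gene → transcript → protein → EC class → KEGG reaction → KEGG compound

restricted to the `is_a` descendants of GO:0008152 (metabolic process)
for one taxon (human, tax 9606, by default).

# The knowledgebase model

Six public sources feed the build: the GO ontology (OBO), NCBI
`gene2go` (gene–GO annotations) and `gene2accession`
(gene–transcript–protein), Expasy `enzyme.dat` (EC nomenclature and
status), two KEGG REST `link` tables (EC–reaction,
reaction–compound), and a pre-fetched two-column EC–protein table. All
parsers accept plain or gzip-compressed files, and every build step is
deterministic: entities and edges are kept in a fixed (C-locale) sort
order, so rebuilding from identical inputs produces a byte-identical
archive. The archive itself is a single gzip-compressed JSON document
with an embedded manifest (tool version, taxon, root term, flags,
optional access date).

Assumptions worth making explicit:

* **Only `is_a` edges define the hierarchy.** `part_of`, `regulates`
  and other relationship types are ignored. `is_a` is the one relation
  whose semantics (subsumption) are uncontroversial for restricting to
  a sub-ontology; including `part_of` would pull in terms that are
  components of metabolic processes without being metabolic processes.
* **Direct annotations only, by default.** A gene annotated to a term
  does not count for the term's ancestors. With true-path propagation
  every ancestor up to the root would share its descendants' compound
  sets, ancestor terms would dominate every result list, and the
  distinction between "terms with an annotated gene" and the full
  sub-ontology would vanish. Propagation remains available
  (`build_knowledgebase(..., propagate = TRUE)`) for users who want
  classical GO semantics.
* **Transferred and deleted EC entries carry no links.** Reaction
  links attached to a non-active EC number in the sources are dropped.
* **Accession versions are stripped everywhere** (`NM_000001.3` →
  `NM_000001`), because the sources disagree on versions and the joins
  must be version-independent.
* **Obsolete terms are excluded** from the sub-ontology; `alt_id`
  accessions are resolved to their primary term on every lookup
  (annotation rows, network queries).

When the EC–protein table is absent the gene→compound chain cannot be
formed at all, so no term has compounds and enrichment is impossible.
The builder then fails with a clear error by default; passing
`require_compounds = FALSE` instead yields a browse-only catalog (all
active ECs and their reactions/compounds retained, flagged
`unfiltered-EC` in the manifest). We chose a hard default failure over
silently producing a knowledgebase that cannot support its main use.

# The test

With `N` the number of distinct compounds linked to at least one
metabolic GO term (the *background universe*), a term with compound
set of size $y$, an input list with $b$ compounds mapped into the
universe, and overlap $x$, the p-value is the hypergeometric upper
tail

$$ p = P[X \ge x], \qquad X \sim \mathrm{Hypergeom}(y,\; a,\; b), $$

computed as `phyper(x - 1, y, a, b, lower.tail = FALSE)`, which
evaluates the survival function directly and is numerically stable in
extreme tails (verified against exhaustive draw enumeration for all
frames with $y + a \le 12$ to $10^{-12}$).

**Choice of the complement $a$.** Two conventions exist: the universe
complement $a = N - y$ (compounds not linked to the term) and the
input-based $a = N - b$. The universe complement is the statistically
correct one — the urn contains the $y$ term compounds and the $N - y$
others, and $b$ is the number of draws — so `run_ora()` always uses
$a = N - y$. Because `hypergeom_upper_tail(x, y, a, b)` is exported,
either call can be reproduced verbatim; for the bundled worked example
(x = 13, y = 61, b = 62, N = 2212) the two differ by about 0.5%.

**Filters.** Three relevance filters run before FDR adjustment:
`x >= min_overlap` (default 3), `gene_count >= min_genes` (default 3),
and `x > min_overlap_fraction * y` (default 0.05, strict inequality).
They remove terms whose apparent enrichment rests on one or two
compounds or on a term with almost no genetic support. Boundary
behaviour: `x = 3` passes the first rule; `x` exactly equal to 5% of
`y` fails the third.

**FDR.** The Benjamini–Hochberg step-up adjustment runs over the
filter-passing terms, so `m` is the filtered count — filtering is part
of the testing protocol, not a post-hoc selection, and adjusting
unfiltered terms would spend FDR budget on terms that can never be
reported. `fdr_all_terms = TRUE` adjusts across all tested terms for
sensitivity analysis. Significance is `q < alpha` (default 0.05).

**Determinism.** Results are sorted by p-value with ties broken by
term accession; permuting the input list never changes any statistic
(property-tested). `-log10(p)` in the impact table floors p at
1e-300 so the transform stays finite.

# Network exports

The *ontology network* contains the significant terms plus all their
`is_a` ancestors up to the root; ancestors that are not themselves
significant carry `significant = false`, and tested terms carry
`neg_log10_p` and `q_value` attributes so Cytoscape can size nodes by
significance. The output is by construction an acyclic sub-DAG of the
ontology.

The *reaction network* of one term contains its genes, their
transcripts, proteins, ECs, the ECs' reactions and those reactions'
compounds, with typed edges (`encodes`, `translates_to`, `catalyzes`,
`participates`, `substrate_product`). KEGG's reactant-pair (atomic
mapping) resource is discontinued, so reaction nodes link to all their
participant compounds rather than to mapped substrate–product pairs;
the edge model keeps a single relation name (`substrate_product`) so a
pair table could be substituted without changing the format. A
`detected =` argument subsets to the compounds observed in a study
(compounds outside the set are removed first, then reactions left
without compounds); the result is always a subgraph of the full
network. Hub cofactors (water, ATP, ...) can be excluded via
`exclude_compounds` — no list is applied by default because what
counts as a cofactor is study-dependent.

SIF files contain one `source TAB relation TAB target` line per edge,
isolated nodes as single-column lines, all lines sorted; the
node-attribute TSV has the union of attribute columns, blank cells for
absent attributes, and numeric values at 6 significant digits.

# The synthetic-data generator

`generate_mock_sources()` writes miniature, format-exact versions of
all six sources: a random `is_a` DAG rooted at GO:0008152 (default 5
terms), 4 genes with 1–2 annotations each, 1–2 transcripts/proteins
per gene, 3 active ECs (plus one transferred and one deleted record),
4 reactions and a 6-compound pool, together with every corner case the
parsers must handle (obsolete term, alt_id, NOT qualifier, foreign
taxon rows, `-` placeholders, glycan links). Generation is a pure
function of the spec and seed, and a `truth.json` written alongside
records the expected knowledgebase — computed by direct set operations
on the tuples the generator decided, independent of the file parsers —
so builds can be checked against an oracle. A default-spec bundle is
also committed under `inst/extdata/mock/` and a test pins the
generator against it byte-for-byte.

What the generator deliberately does **not** emulate: realistic
pathway topology, compound chemistry, the power-law degree
distribution of real gene–reaction networks, or realistic ontology
depth. Passing tests therefore demonstrate correctness of parsing,
graph assembly, statistics and export contracts — not biological
plausibility of results on real sources. The enumeration oracle for
the hypergeometric tail covers all population sizes up to 12; the
worked-example knowledgebase (`worked_example_kb()`) covers the
realistic scale (universe 2,212) with a known closed-form frame.

Problem sizes in the test suite (5–8 terms, ≤ 8 compounds, universe
≤ 2,212) were chosen so the whole suite exercises every code path,
including the exhaustive oracles, in well under a minute.

# Limitations

* Coverage is bounded by KEGG: compounds without a C-number, and
  C-numbers not linked to any reaction/EC, can never contribute.
* The EC–protein linkage must be supplied as a pre-fetched table; its
  quality bounds the gene→compound chain.
* GO term-name redundancy can inflate result lists (several
  near-synonymous processes sharing compound sets).
* Direct-annotation mode undercounts broad terms by design; enable
  propagation when ancestor-level statements are wanted.
* The tool tests over-representation of an unweighted list; it is not
  a quantitative (abundance-weighted) or ranked (GSEA-style) method,
  and upstream significance selection is the caller's responsibility.
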