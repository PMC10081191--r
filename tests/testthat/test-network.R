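sig_report <- function(kb, ids) {
  run_ora(kb, ids, min_overlap = 1, min_genes = 1,
          min_overlap_fraction = 0)
}

test_that("the ontology network spans significant terms plus their ancestors", {
  kb <- small_ora_kb()
  rep <- sig_report(kb, c("C00001", "C00002", "C00003"))
  # only process A (p = 0.05, q = 0.1) clears alpha = 0.2; B (p = 1) does not
  net <- go_ontology_network(rep, kb, alpha = 0.2)
  expect_identical(net$nodes$node_id, c("GO:0008152", "GO:1000001"))
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$source, "GO:1000001")
  expect_identical(net$edges$target, "GO:0008152")
  expect_identical(net$edges$relation, "is_a")
  sig <- setNames(net$nodes$significant, net$nodes$node_id)
  expect_true(sig[["GO:1000001"]])
  expect_false(sig[["GO:0008152"]])
  expect_equal(net$nodes$neg_log10_p[net$nodes$node_id == "GO:1000001"],
               -log10(0.05), tolerance = 1e-9)
})

test_that("two significant siblings sharing a parent give 4 nodes and 3 edges", {
  kb <- small_ora_kb()
  # add an intermediate parent shared by A and B under the root
  kb$terms[["GO:1000009"]] <- list(
    term_id = "GO:1000009", name = "shared parent",
    namespace = "biological_process", parents = "GO:0008152",
    alt_ids = character(0), obsolete = FALSE)
  kb$terms[["GO:1000001"]]$parents <- "GO:1000009"
  kb$terms[["GO:1000002"]]$parents <- "GO:1000009"
  # with two draws both terms get p < 1 (A: 0.8, B: 14/15), so both
  # clear alpha = 0.99 after BH over the two of them
  rep <- sig_report(kb, c("C00001", "C00004"))
  net <- go_ontology_network(rep, kb, alpha = 0.99)
  expect_identical(nrow(net$nodes), 4L)
  expect_identical(nrow(net$edges), 3L)
})

test_that("an impossible alpha yields an empty network with a notice, not an error", {
  kb <- small_ora_kb()
  rep <- sig_report(kb, c("C00001", "C00002", "C00003"))
  expect_message(net <- go_ontology_network(rep, kb, alpha = 1e-12),
                 "no significant")
  expect_identical(nrow(net$nodes), 0L)
  expect_identical(nrow(net$edges), 0L)
})

test_that("ontology networks are acyclic sub-DAGs of the is_a hierarchy", {
  dir <- withr::local_tempdir()
  kb <- build_knowledgebase(generate_mock_sources(
    fixture_spec(n_terms = 8L, seed = 5L), dir))
  # input = smallest term's compound set, so that term is enriched
  sizes <- lengths(kb$term_to_compounds)
  rep <- sig_report(kb, kb$term_to_compounds[[names(which.min(sizes))]])
  net <- go_ontology_network(rep, kb, alpha = 0.999)
  expect_true(nrow(net$edges) > 0L)
  expect_true(all(net$edges$relation == "is_a"))
  # every edge is a real parent link of the ontology
  for (i in seq_len(nrow(net$edges))) {
    expect_true(net$edges$target[i] %in%
                  kb$terms[[net$edges$source[i]]]$parents)
  }
  g <- igraph::graph_from_data_frame(net$edges[, c("source", "target")])
  expect_true(igraph::is_dag(g))
})

test_that("the reaction network traces the full entity chain of the fixture", {
  kb <- build_two_gene_kb()
  net <- reaction_network(kb, "GO:1000001")
  kinds <- split(net$nodes$node_id, net$nodes$entity_kind)
  expect_identical(kinds$gene, "1001")
  expect_identical(kinds$transcript, "NM_000001")
  expect_identical(kinds$protein, "NP_000001")
  expect_identical(kinds$enzyme, "1.1.1.1")
  expect_identical(kinds$reaction, "R00001")
  expect_identical(kinds$compound, c("C00001", "C00002"))
  rel <- net$edges$relation
  expect_setequal(unique(rel), c("encodes", "translates_to", "catalyzes",
                                 "participates", "substrate_product"))
  expect_identical(nrow(net$edges), 6L)  # 4 chain edges + 2 compounds
  # gene labels use the symbol
  expect_identical(net$nodes$label[net$nodes$entity_kind == "gene"],
                   "GENEA")
})

test_that("alt_id queries resolve and unknown terms are lookup errors", {
  kb <- build_two_gene_kb()
  net <- reaction_network(kb, "GO:0200001")   # alt of GO:1000001
  expect_true("1001" %in% net$nodes$node_id)
  expect_error(reaction_network(kb, "GO:9999999"),
               class = "metago_lookup_error")
})

test_that("detected-compound subsetting drops compounds then empty reactions", {
  kb <- build_two_gene_kb()
  full <- reaction_network(kb, "GO:1000001")
  part <- reaction_network(kb, "GO:1000001", detected = "C00001")
  expect_false("C00002" %in% part$nodes$node_id)
  expect_true("R00001" %in% part$nodes$node_id)
  det <- setNames(part$nodes$detected, part$nodes$node_id)
  expect_true(det[["C00001"]])
  # empty detected set: reactions vanish, upstream layers remain
  none <- reaction_network(kb, "GO:1000001", detected = character(0))
  expect_identical(sum(none$nodes$entity_kind %in%
                         c("reaction", "compound")), 0L)
  expect_setequal(none$nodes$entity_kind,
                  c("gene", "transcript", "protein", "enzyme"))
  # any detected-restricted network is a subgraph of the full one
  for (net in list(part, none)) {
    expect_true(all(net$nodes$node_id %in% full$nodes$node_id))
    key <- function(e) paste(e$source, e$relation, e$target)
    expect_true(all(key(net$edges) %in% key(full$edges)))
  }
})

test_that("suppressing the protein layer collapses gene-catalyzes-EC", {
  kb <- build_two_gene_kb()
  net <- reaction_network(kb, "GO:1000001", include_proteins = FALSE)
  expect_false(any(net$nodes$entity_kind %in% c("transcript", "protein")))
  expect_true(any(net$edges$source == "1001" &
                    net$edges$relation == "catalyzes" &
                    net$edges$target == "1.1.1.1"))
})

test_that("SIF output is exact, sorted and round-trips the edge multiset", {
  nodes <- data.frame(node_id = c("A", "B", "N"),
                      entity_kind = "go_term", label = c("a", "b", "n"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(source = "A", relation = "is_a", target = "B",
                      stringsAsFactors = FALSE)
  net <- metago:::new_network(nodes, edges, kind = "ontology")
  path <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, path)
  expect_identical(readLines(path), c("A\tis_a\tB", "N"))

  kb <- build_two_gene_kb()
  rnet <- reaction_network(kb, "GO:1000002")
  write_sif(rnet, path)
  back <- read_sif(path)
  expect_identical(nrow(back$edges), nrow(rnet$edges))
  expect_setequal(paste(back$edges$source, back$edges$relation,
                        back$edges$target),
                  paste(rnet$edges$source, rnet$edges$relation,
                        rnet$edges$target))
})

test_that("node-attribute files agree with the SIF node set and format numbers to 6 significant digits", {
  kb <- small_ora_kb()
  rep <- sig_report(kb, c("C00001", "C00002", "C00003"))
  net <- go_ontology_network(rep, kb, alpha = 0.99)
  sif <- withr::local_tempfile(fileext = ".sif")
  attrs <- withr::local_tempfile(fileext = ".tsv")
  write_sif(net, sif)
  write_node_attributes(net, attrs)
  tab <- read.delim(attrs, check.names = FALSE,
                    colClasses = "character")
  expect_identical(names(tab)[1:3], c("node_id", "entity_kind", "label"))
  parsed <- read_sif(sif)
  sif_nodes <- unique(c(parsed$edges$source, parsed$edges$target,
                        parsed$isolated))
  expect_setequal(tab$node_id, sif_nodes)
  expect_setequal(tab$node_id, net$nodes$node_id)
  # untested ancestor rows leave numeric cells blank
  expect_identical(tab$q_value[tab$node_id == "GO:0008152"], "")
  # 6 significant digits
  p <- rep$results$p_value[rep$results$term_id == "GO:1000001"]
  expect_identical(tab$neg_log10_p[tab$node_id == "GO:1000001"],
                   formatC(signif(-log10(p), 6), format = "g", digits = 6))
})
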