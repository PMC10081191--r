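# Node/edge container serialized to Cytoscape SIF + node attributes.
# Nodes: data.frame(node_id, entity_kind, label, <attribute columns>).
# Edges: data.frame(source, relation, target).

new_network <- function(nodes, edges, kind = c("ontology", "reaction")) {
  kind <- match.arg(kind)
  stopifnot(all(c("node_id", "entity_kind", "label") %in% names(nodes)))
  if (anyDuplicated(nodes$node_id)) {
    build_error("duplicate node ids in network")
  }
  if (nrow(edges)) {
    stopifnot(all(c("source", "relation", "target") %in% names(edges)))
    ok <- edges$source %in% nodes$node_id & edges$target %in% nodes$node_id
    if (!all(ok)) build_error("network edge endpoints missing from node set")
    edges <- edges[edges$source != edges$target, , drop = FALSE]
    # undirected duplicate suppression on (source, relation, target)
    lo <- pmin(edges$source, edges$target)
    hi <- pmax(edges$source, edges$target)
    edges <- edges[!duplicated(paste(lo, edges$relation, hi, sep = "\r")), ,
                   drop = FALSE]
  }
  nodes <- nodes[order(nodes$node_id, method = "radix"), , drop = FALSE]
  rownames(nodes) <- NULL
  if (nrow(edges)) {
    edges <- order_df(edges[, c("source", "relation", "target")])
  } else {
    edges <- data.frame(source = character(0), relation = character(0),
                        target = character(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, kind = kind),
            class = "metago_network")
}

node_row <- function(node_id, entity_kind, label, ...) {
  data.frame(node_id = node_id, entity_kind = entity_kind, label = label,
             ..., stringsAsFactors = FALSE)
}

#' GO ontology network of significant terms
#'
#' Builds the sub-DAG of the ontology spanned by the significantly
#' over-represented terms (q-value below `alpha`) and all their `is_a`
#' ancestors up to the metabolic root. Ancestors that are not
#' themselves significant carry `significant = FALSE`; terms that were
#' tested carry their `neg_log10_p` and `q_value` as node attributes
#' (node size in Cytoscape can then encode significance).
#'
#' @param report A `metago_ora` report.
#' @param kb The `metago_kb` the report was computed against.
#' @param alpha Significance threshold on the q-value (defaults to the
#'   report's own alpha).
#' @return A `metago_network` of kind `"ontology"`; empty (with a
#'   message) when no term is significant.
#' @export
go_ontology_network <- function(report, kb, alpha = NULL) {
  stopifnot(inherits(report, "metago_ora"), inherits(kb, "metago_kb"))
  alpha <- alpha %||% report$query$alpha
  res <- report$results
  sig <- res$term_id[!is.na(res$q_value) & res$q_value < alpha]
  if (!length(sig)) {
    message("no significant GO terms at alpha = ", alpha,
            "; returning empty network")
    return(new_network(
      node_row(character(0), character(0), character(0)),
      data.frame(source = character(0), relation = character(0),
                 target = character(0), stringsAsFactors = FALSE),
      kind = "ontology"))
  }
  node_ids <- sort_c(union(sig, go_ancestors(kb$terms, sig)))
  tested <- match(node_ids, res$term_id)
  nodes <- node_row(
    node_id = node_ids,
    entity_kind = "go_term",
    label = vapply(node_ids, function(t) kb$terms[[t]]$name %||% t,
                   character(1)),
    significant = node_ids %in% sig,
    neg_log10_p = ifelse(is.na(tested), NA_real_,
                         -log10(pmax(res$p_value[tested], 1e-300))),
    q_value = ifelse(is.na(tested), NA_real_, res$q_value[tested]),
    url = paste0("https://amigo.geneontology.org/amigo/term/", node_ids)
  )
  inside <- function(t) kb$terms[[t]]$parents[
    kb$terms[[t]]$parents %in% node_ids]
  edges <- do.call(rbind, lapply(node_ids, function(t) {
    p <- inside(t)
    if (length(p)) data.frame(source = t, relation = "is_a", target = p,
                              stringsAsFactors = FALSE)
  })) %||% data.frame(source = character(0), relation = character(0),
                      target = character(0), stringsAsFactors = FALSE)
  new_network(nodes, edges, kind = "ontology")
}

#' Focused metabolic reaction network for one GO term
#'
#' Collects the genes annotated to a GO term together with their
#' transcripts, proteins, EC classes, those ECs' reactions and the
#' reactions' compounds, and connects them along the knowledgebase
#' chain: gene `encodes` transcript, transcript `translates_to`
#' protein, protein `catalyzes` EC (collapsed to gene `catalyzes` EC
#' when `include_proteins = FALSE`), EC `participates` reaction,
#' reaction `substrate_product` compound.
#'
#' When `detected` is supplied, compounds outside it are removed and
#' reactions left with no compound are dropped — the partial network
#' for only the compounds observed in a study. Hub cofactors (water,
#' protons, ...) can be excluded via `exclude_compounds` to keep the
#' graph readable.
#'
#' @param kb A `metago_kb` object.
#' @param term_id GO accession (alt_ids are resolved).
#' @param detected Optional character vector of detected KEGG compound
#'   accessions; `NULL` keeps all compounds.
#' @param include_proteins Keep the transcript/protein layers
#'   (default `TRUE`).
#' @param exclude_compounds Compound accessions to drop unconditionally.
#' @return A `metago_network` of kind `"reaction"`. Compound nodes
#'   carry a `detected` attribute when `detected` is given; all nodes
#'   carry a cross-reference `url` attribute.
#' @export
reaction_network <- function(kb, term_id, detected = NULL,
                             include_proteins = TRUE,
                             exclude_compounds = character(0)) {
  stopifnot(inherits(kb, "metago_kb"))
  term_id <- resolve_alt_ids(term_id, kb$alt_to_primary)
  genes <- kb$term_to_genes[[term_id]]
  if (is.null(kb$terms[[term_id]]) || is.null(genes) || !length(genes)) {
    lookup_error("GO term '%s' not found in knowledgebase or has no genes",
                 term_id)
  }
  e <- kb$edges
  g_t <- e$gene_transcript[e$gene_transcript$gene_id %in% genes, ,
                           drop = FALSE]
  t_p <- e$transcript_protein[
    e$transcript_protein$rna_accession %in% g_t$rna_accession, ,
    drop = FALSE]
  p_e <- e$protein_ec[e$protein_ec$protein_accession %in%
                        t_p$protein_accession, , drop = FALSE]
  ecs <- sort_c(unique(p_e$ec_number))
  e_r <- e$ec_reaction[e$ec_reaction$ec_number %in% ecs, , drop = FALSE]
  r_c <- e$reaction_compound[
    e$reaction_compound$reaction_id %in% e_r$reaction_id, , drop = FALSE]
  r_c <- r_c[!r_c$compound_id %in% exclude_compounds, , drop = FALSE]
  if (!is.null(detected)) {
    r_c <- r_c[r_c$compound_id %in% detected, , drop = FALSE]
  }
  reactions <- sort_c(unique(r_c$reaction_id))
  e_r <- e_r[e_r$reaction_id %in% reactions, , drop = FALSE]
  compounds <- sort_c(unique(r_c$compound_id))

  gene_sym <- kb$genes$symbol[match(genes, kb$genes$gene_id)]
  nodes <- rbind(
    node_row(as.character(genes), "gene",
             ifelse(is.na(gene_sym), as.character(genes), gene_sym),
             url = paste0("https://www.ncbi.nlm.nih.gov/gene/", genes)),
    if (include_proteins && nrow(g_t)) {
      tr <- sort_c(unique(g_t$rna_accession))
      node_row(tr, "transcript", tr,
               url = paste0("https://www.ncbi.nlm.nih.gov/nuccore/", tr))
    },
    if (include_proteins && nrow(t_p)) {
      pr <- sort_c(unique(t_p$protein_accession))
      node_row(pr, "protein", pr,
               url = paste0("https://www.ncbi.nlm.nih.gov/protein/", pr))
    },
    if (length(ecs)) {
      node_row(ecs, "enzyme", ecs,
               url = paste0("https://enzyme.expasy.org/EC/", ecs))
    },
    if (length(reactions)) {
      node_row(reactions, "reaction", reactions,
               url = paste0("https://www.kegg.jp/entry/", reactions))
    },
    if (length(compounds)) {
      node_row(compounds, "compound", compounds,
               url = paste0("https://www.kegg.jp/entry/", compounds))
    }
  )
  if (!is.null(detected)) {
    nodes$detected <- ifelse(nodes$entity_kind == "compound",
                             nodes$node_id %in% detected, NA)
  }

  mk <- function(s, r, t) {
    if (!length(s)) return(NULL)
    data.frame(source = as.character(s), relation = r,
               target = as.character(t), stringsAsFactors = FALSE)
  }
  if (include_proteins) {
    chain <- rbind(
      mk(g_t$gene_id, "encodes", g_t$rna_accession),
      mk(t_p$rna_accession, "translates_to", t_p$protein_accession),
      mk(p_e$protein_accession, "catalyzes", p_e$ec_number)
    )
  } else {
    # collapse to gene -> EC when the protein layer is suppressed
    g_p <- merge(g_t, t_p, by = "rna_accession")
    g_e <- unique(merge(g_p, p_e,
                        by = "protein_accession")[, c("gene_id", "ec_number")])
    chain <- mk(g_e$gene_id, "catalyzes", g_e$ec_number)
  }
  edges <- rbind(
    chain,
    mk(e_r$ec_number, "participates", e_r$reaction_id),
    mk(r_c$reaction_id, "substrate_product", r_c$compound_id)
  ) %||% data.frame(source = character(0), relation = character(0),
                    target = character(0), stringsAsFactors = FALSE)
  new_network(nodes, edges, kind = "reaction")
}

#' Write a network as a Cytoscape SIF file
#'
#' One tab-separated line `source relation target` per edge; nodes that
#' take part in no edge are emitted as single-column lines (the SIF
#' convention for isolated nodes). Lines are sorted, so output is
#' deterministic.
#'
#' @param network A `metago_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "metago_network"))
  ed <- network$edges
  edge_lines <- if (nrow(ed)) {
    paste(ed$source, ed$relation, ed$target, sep = "\t")
  } else character(0)
  isolated <- setdiff(network$nodes$node_id, c(ed$source, ed$target))
  writeLines(c(sort_c(edge_lines), sort_c(isolated)), path)
  invisible(path)
}

#' Write a network's node-attribute table
#'
#' Tab-separated table with header `node_id`, `entity_kind`, `label`,
#' then one column per attribute (union over nodes; blank when a node
#' lacks the attribute). Rows are sorted by node id; numeric attributes
#' are rendered with 6 significant digits.
#'
#' @param network A `metago_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_node_attributes <- function(network, path) {
  stopifnot(inherits(network, "metago_network"))
  nd <- network$nodes
  attrs <- setdiff(names(nd), c("node_id", "entity_kind", "label"))
  nd <- nd[order(nd$node_id, method = "radix"),
           c("node_id", "entity_kind", "label", sort_c(attrs)),
           drop = FALSE]
  fmt <- function(col) {
    out <- if (is.numeric(col)) {
      formatC(signif(col, 6), format = "g", digits = 6)
    } else if (is.logical(col)) {
      ifelse(col, "true", "false")
    } else {
      as.character(col)
    }
    out[is.na(col)] <- ""
    as.character(out)
  }
  lines <- paste(names(nd), collapse = "\t")
  if (nrow(nd)) {
    cells <- matrix(unlist(lapply(nd, fmt)), nrow = nrow(nd))
    lines <- c(lines, apply(cells, 1L, paste, collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.metago_network <- function(x, ...) {
  cat(sprintf("<metago %s network> %d nodes, %d edges\n",
              x$kind, nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) {
    print(table(x$nodes$entity_kind))
  }
  invisible(x)
}
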