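#' Describe the raw source files for a knowledgebase build
#'
#' Bundles the paths of the five mandatory source files (GO ontology in
#' OBO format, NCBI gene2go and gene2accession, Expasy enzyme.dat, and
#' the two KEGG REST link tables) plus the optional pre-fetched
#' EC-to-protein table. All paths must exist and be readable.
#'
#' @param obo,gene2go,gene2accession,enzyme_dat,ec2reaction,reaction2compound
#'   Paths to the mandatory source files (plain or gzipped).
#' @param ec2protein Optional path to a two-column EC/protein-accession
#'   table; when `NULL` the build keeps all active EC classes
#'   (see [build_knowledgebase()]).
#' @return An object of class `metago_sources`.
#' @export
source_bundle <- function(obo, gene2go, gene2accession, enzyme_dat,
                          ec2reaction, reaction2compound,
                          ec2protein = NULL) {
  paths <- list(obo = obo, gene2go = gene2go,
                gene2accession = gene2accession, enzyme_dat = enzyme_dat,
                ec2reaction = ec2reaction,
                reaction2compound = reaction2compound)
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) {
      build_error("source file '%s' (%s) is missing or unreadable",
                  paths[[nm]], nm)
    }
  }
  if (!is.null(ec2protein) && !file.exists(ec2protein)) {
    build_error("source file '%s' (ec2protein) is missing or unreadable",
                ec2protein)
  }
  structure(c(paths, list(ec2protein = ec2protein)),
            class = "metago_sources")
}

#' Locate source files by their conventional names in a directory
#'
#' Looks for `go.obo`, `gene2go`, `gene2accession`, `enzyme.dat`,
#' `ec2reaction.tsv`, `reaction2compound.tsv` and the optional
#' `ec2protein.tsv`, each possibly carrying a `.tsv` and/or `.gz`
#' suffix.
#'
#' @param dir Directory holding the source files.
#' @return An object of class `metago_sources`.
#' @export
find_sources <- function(dir) {
  locate <- function(stem, required = TRUE) {
    cands <- c(stem, paste0(stem, ".gz"), paste0(stem, ".tsv"),
               paste0(stem, ".tsv.gz"))
    for (f in file.path(dir, cands)) if (file.exists(f)) return(f)
    if (required) {
      build_error("required source file '%s' not found in %s", stem, dir)
    }
    NULL
  }
  source_bundle(
    obo = locate("go.obo"),
    gene2go = locate("gene2go"),
    gene2accession = locate("gene2accession"),
    enzyme_dat = locate("enzyme.dat"),
    ec2reaction = locate("ec2reaction"),
    reaction2compound = locate("reaction2compound"),
    ec2protein = locate("ec2protein", required = FALSE)
  )
}

#' Build the metabolic Gene Ontology knowledgebase
#'
#' Integrates the raw sources into one graph restricted to the metabolic
#' sub-ontology of one taxon:
#' \enumerate{
#'   \item keep GO terms in the `is_a` descendant closure of `root_id`
#'     (obsolete terms excluded);
#'   \item keep genes of `tax_id` directly annotated to at least one
#'     kept term (GO accessions in gene2go are resolved through
#'     `alt_id`s first);
#'   \item keep the transcripts and proteins of kept genes;
#'   \item keep active EC classes linked to kept proteins through the
#'     EC-to-protein table; when that table is absent, keep every active
#'     EC class and flag the build `unfiltered_ec`;
#'   \item keep reactions of kept ECs and the KEGG compounds of kept
#'     reactions (reactions without any compound are dropped);
#'   \item derive `term_to_compounds`: for each term, the union of
#'     compounds reachable from its annotated genes along
#'     gene\eqn{\to}protein\eqn{\to}EC\eqn{\to}reaction\eqn{\to}compound.
#' }
#' By default only direct annotations count: a gene annotated to a term
#' does not count for that term's ancestors. Set `propagate = TRUE` for
#' classical true-path propagation up the `is_a` hierarchy.
#'
#' The background universe size `background_n` is the number of distinct
#' compounds linked to at least one kept GO term; it is the `N` of the
#' downstream hypergeometric test.
#'
#' @param sources A `metago_sources` bundle (see [source_bundle()]).
#' @param tax_id NCBI taxonomy id (default 9606, human).
#' @param root_id Sub-ontology root (default GO:0008152, metabolic
#'   process).
#' @param propagate Propagate annotations to `is_a` ancestors
#'   (default `FALSE`).
#' @param require_compounds Error when the resulting GO-linked compound
#'   universe is empty (default `TRUE`); pass `FALSE` to allow a
#'   browse-only knowledgebase without enrichment support.
#' @param accessed Optional date string recorded in the build manifest
#'   (when the sources were retrieved). Left out by default so rebuilds
#'   from identical inputs are byte-identical.
#' @return An object of class `metago_kb`.
#' @export
build_knowledgebase <- function(sources, tax_id = 9606L,
                                root_id = "GO:0008152",
                                propagate = FALSE,
                                require_compounds = TRUE,
                                accessed = NULL) {
  stopifnot(inherits(sources, "metago_sources"))
  onto <- parse_go_obo(sources$obo)
  kept_terms <- metabolic_subontology(onto, root_id)
  terms <- onto$terms[kept_terms]
  # restrict parent links to the kept sub-ontology
  terms <- lapply(terms, function(t) {
    t$parents <- sort_c(intersect(t$parents, kept_terms))
    t
  })
  alt <- onto$alt_to_primary[onto$alt_to_primary %in% kept_terms]

  g2g <- parse_gene2go(sources$gene2go, tax_id)
  g2g$term_id <- resolve_alt_ids(g2g$term_id, onto$alt_to_primary)
  g2g <- unique(g2g[g2g$term_id %in% kept_terms, , drop = FALSE])
  if (propagate) {
    extra <- lapply(seq_len(nrow(g2g)), function(i) {
      anc <- intersect(go_ancestors(terms, g2g$term_id[i]), kept_terms)
      if (length(anc)) data.frame(gene_id = g2g$gene_id[i], term_id = anc,
                                  stringsAsFactors = FALSE)
    })
    g2g <- unique(rbind(g2g, do.call(rbind, extra)))
  }
  g2g <- g2g[order(g2g$gene_id, g2g$term_id, method = "radix"), ,
             drop = FALSE]
  kept_genes <- sort(unique(g2g$gene_id))

  g2a <- parse_gene2accession(sources$gene2accession, tax_id)
  g2a <- g2a[g2a$gene_id %in% kept_genes, , drop = FALSE]
  transcripts <- sort_c(unique(g2a$rna_accession[!is.na(g2a$rna_accession)]))
  proteins <- sort_c(unique(
    g2a$protein_accession[!is.na(g2a$protein_accession)]))
  symbols <- g2a$symbol[!is.na(g2a$symbol)]
  names(symbols) <- g2a$gene_id[!is.na(g2a$symbol)]

  enz <- parse_enzyme_dat(sources$enzyme_dat)
  active_ecs <- enz$ec_number[enz$status == "active"]

  if (!is.null(sources$ec2protein)) {
    e2p <- parse_ec2protein(sources$ec2protein)
    e2p <- e2p[e2p$protein_accession %in% proteins &
                 e2p$ec_number %in% active_ecs, , drop = FALSE]
    kept_ecs <- sort_c(unique(e2p$ec_number))
    unfiltered_ec <- FALSE
  } else {
    e2p <- data.frame(ec_number = character(0),
                      protein_accession = character(0),
                      stringsAsFactors = FALSE)
    kept_ecs <- sort_c(active_ecs)
    unfiltered_ec <- TRUE
  }

  ec2rn <- parse_kegg_link(sources$ec2reaction, "ec", "rn")
  ec2rn <- ec2rn[ec2rn$from_id %in% kept_ecs, , drop = FALSE]
  rn2cpd <- parse_kegg_link(sources$reaction2compound, "rn", "cpd")
  rn2cpd <- rn2cpd[rn2cpd$from_id %in% ec2rn$to_id, , drop = FALSE]
  # a reaction with no compound participant carries no information
  kept_reactions <- sort_c(unique(rn2cpd$from_id))
  ec2rn <- ec2rn[ec2rn$to_id %in% kept_reactions, , drop = FALSE]
  compounds <- sort_c(unique(rn2cpd$to_id))

  edges <- list(
    gene_go = g2g,
    gene_transcript = order_df(unique(
      g2a[!is.na(g2a$rna_accession), c("gene_id", "rna_accession")])),
    transcript_protein = order_df(unique(
      g2a[!is.na(g2a$rna_accession) & !is.na(g2a$protein_accession),
          c("rna_accession", "protein_accession")])),
    protein_ec = order_df(
      e2p[, c("protein_accession", "ec_number"), drop = FALSE]),
    ec_reaction = order_df(data.frame(
      ec_number = ec2rn$from_id, reaction_id = ec2rn$to_id,
      stringsAsFactors = FALSE)),
    reaction_compound = order_df(data.frame(
      reaction_id = rn2cpd$from_id, compound_id = rn2cpd$to_id,
      stringsAsFactors = FALSE))
  )

  # gene -> compound reachability along the full chain
  gene_prot <- unique(g2a[!is.na(g2a$protein_accession),
                          c("gene_id", "protein_accession")])
  gene_ec <- unique(merge(gene_prot, e2p, by = "protein_accession")[
    , c("gene_id", "ec_number")])
  gene_rn <- unique(merge(gene_ec, edges$ec_reaction,
                          by = "ec_number")[, c("gene_id", "reaction_id")])
  gene_cpd <- unique(merge(gene_rn, edges$reaction_compound,
                           by = "reaction_id")[, c("gene_id", "compound_id")])
  term_cpd <- unique(merge(g2g, gene_cpd, by = "gene_id")[
    , c("term_id", "compound_id")])

  term_to_compounds <- lapply(
    split(term_cpd$compound_id, term_cpd$term_id), function(x) sort_c(unique(x)))
  term_to_compounds <- term_to_compounds[sort_c(names(term_to_compounds))]
  term_to_genes <- lapply(split(g2g$gene_id, g2g$term_id),
                          function(x) sort(unique(x)))
  term_to_genes <- term_to_genes[sort_c(names(term_to_genes))]

  universe <- sort_c(unique(unlist(term_to_compounds, use.names = FALSE)))
  if (require_compounds && length(universe) == 0L) {
    build_error("no GO-linked compounds: the knowledgebase compound universe is empty%s",
                if (unfiltered_ec)
                  " (no EC-to-protein table was provided, so genes cannot reach compounds)"
                else "")
  }

  genes <- data.frame(
    gene_id = kept_genes,
    symbol = ifelse(as.character(kept_genes) %in% names(symbols),
                    symbols[as.character(kept_genes)], NA_character_),
    tax_id = as.integer(tax_id),
    stringsAsFactors = FALSE, row.names = NULL
  )

  manifest <- list(
    format = "metago-kb-json", format_version = 1L,
    tool = "metago",
    tool_version = as.character(utils::packageVersion("metago")),
    tax_id = as.integer(tax_id), root_id = root_id,
    propagate = propagate, unfiltered_ec = unfiltered_ec,
    accessed = accessed
  )

  structure(list(
    terms = terms,
    alt_to_primary = alt,
    genes = genes,
    transcripts = transcripts,
    proteins = proteins,
    enzymes = enz[enz$ec_number %in% kept_ecs |
                    enz$status != "active", , drop = FALSE],
    reactions = kept_reactions,
    compounds = data.frame(compound_id = compounds, name = NA_character_,
                           stringsAsFactors = FALSE),
    edges = edges,
    term_to_compounds = term_to_compounds,
    term_to_genes = term_to_genes,
    universe = universe,
    background_n = length(universe),
    tax_id = as.integer(tax_id),
    root_id = root_id,
    propagate = propagate,
    unfiltered_ec = unfiltered_ec,
    manifest = manifest
  ), class = "metago_kb")
}

order_df <- function(df) {
  if (!nrow(df)) {
    rownames(df) <- NULL
    return(df)
  }
  ord <- do.call(order, c(unname(as.list(df)), list(method = "radix")))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Knowledgebase version string
#'
#' One-line identifier of a knowledgebase build (format version, tool
#' version, taxon, root term, flags), carried into analysis reports.
#'
#' @param kb A `metago_kb` object.
#' @return Character scalar.
#' @export
kb_version <- function(kb) {
  m <- kb$manifest
  sprintf("%s/%d %s-%s tax:%d root:%s%s%s%s",
          m$format, m$format_version, m$tool, m$tool_version, m$tax_id,
          m$root_id,
          if (isTRUE(m$propagate)) " propagate" else "",
          if (isTRUE(m$unfiltered_ec)) " unfiltered-EC" else "",
          if (!is.null(m$accessed)) paste0(" accessed:", m$accessed) else "")
}

#' Entity counts of a knowledgebase
#'
#' Tabulates the content of a built knowledgebase: metabolic GO terms,
#' terms with at least one annotated gene, terms with at least one
#' linked compound, genes, transcripts, proteins, active EC classes,
#' reactions, compounds, and the background universe size.
#'
#' @param kb A `metago_kb` object.
#' @return data.frame with columns `metric` and `count`.
#' @export
kb_statistics <- function(kb) {
  stopifnot(inherits(kb, "metago_kb"))
  data.frame(
    metric = c("go_terms_metabolic", "go_terms_with_gene",
               "go_terms_with_compound", "genes", "transcripts",
               "proteins", "ec_numbers", "reactions", "compounds",
               "background_n"),
    count = c(length(kb$terms), length(kb$term_to_genes),
              length(kb$term_to_compounds), nrow(kb$genes),
              length(kb$transcripts), length(kb$proteins),
              sum(kb$enzymes$status == "active"), length(kb$reactions),
              nrow(kb$compounds), kb$background_n),
    stringsAsFactors = FALSE
  )
}

#' @export
print.metago_kb <- function(x, ...) {
  cat("<metago knowledgebase>", kb_version(x), "\n")
  s <- kb_statistics(x)
  cat(paste0("  ", format(s$metric, width = 24), s$count, collapse = "\n"),
      "\n")
  invisible(x)
}
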