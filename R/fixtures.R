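# Deterministic generator of miniature, syntactically exact source
# files (OBO, gene2go, gene2accession, enzyme.dat, KEGG link tables,
# EC-to-protein table) plus a machine-readable "truth" description of
# the knowledgebase they should yield. The generated files exercise the
# corner cases of every parser (obsolete terms, alt_ids, NOT
# qualifiers, other taxa, placeholder accessions, transferred/deleted
# EC entries, glycan links) without triggering any parser warning. The
# truth file is computed by direct set operations on the tuples the
# generator decided, independently of the file parsers, so it can serve
# as an oracle for build_knowledgebase().

#' Parameters of a mock source bundle
#'
#' @param n_terms Number of metabolic GO terms under the root
#'   (excluding the root itself).
#' @param n_genes Number of annotated genes.
#' @param n_ecs Number of active EC classes.
#' @param n_reactions Number of KEGG reactions.
#' @param n_compounds Number of KEGG compounds to draw from.
#' @param seed Random seed; generation is a pure function of the spec.
#' @param tax_id Taxon of the generated annotations.
#' @return A list of class `metago_fixture_spec`.
#' @export
fixture_spec <- function(n_terms = 5L, n_genes = 4L, n_ecs = 3L,
                         n_reactions = 4L, n_compounds = 6L, seed = 42L,
                         tax_id = 9606L) {
  stopifnot(n_terms >= 1L, n_genes >= 1L, n_ecs >= 1L, n_reactions >= 1L,
            n_compounds >= 1L)
  structure(list(n_terms = as.integer(n_terms),
                 n_genes = as.integer(n_genes),
                 n_ecs = as.integer(n_ecs),
                 n_reactions = as.integer(n_reactions),
                 n_compounds = as.integer(n_compounds),
                 seed = as.integer(seed),
                 tax_id = as.integer(tax_id)),
            class = "metago_fixture_spec")
}

ROOT_GO <- "GO:0008152"

#' Generate miniature knowledgebase source files
#'
#' Writes, into `out_dir`: `go.obo` (a random `is_a` DAG rooted at
#' GO:0008152, plus one obsolete term, one alt_id and one term outside
#' the metabolic sub-ontology), `gene2go` and `gene2accession` in the
#' NCBI dialects (with header lines, another-taxon rows, a NOT-qualified
#' row and `-` placeholders), `enzyme.dat` with active, transferred and
#' deleted records, `ec2protein.tsv`, and the two KEGG REST link tables
#' `ec2reaction.tsv` / `reaction2compound.tsv` (with a glycan row).
#' Alongside them, `truth.json` records the exact knowledgebase a build
#' from these files must produce.
#'
#' Output is byte-identical for identical specs.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Writable output directory (created if needed).
#' @return The `metago_sources` bundle for the written files, with the
#'   truth-file path attached as attribute `truth`.
#' @export
generate_mock_sources <- function(spec = fixture_spec(), out_dir) {
  stopifnot(inherits(spec, "metago_fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_local_seed(spec$seed, {
    terms <- sprintf("GO:%07d", 1000000L + seq_len(spec$n_terms))
    genes <- 1000L + seq_len(spec$n_genes)
    ecs <- sprintf("1.1.1.%d", seq_len(spec$n_ecs))
    reactions <- sprintf("R%05d", seq_len(spec$n_reactions))
    compounds <- sprintf("C%05d", seq_len(spec$n_compounds))
    alt_id <- "GO:0200001"
    obsolete_id <- "GO:0900001"
    outside_id <- "GO:0990001"   # no path to the metabolic root

    # --- ontology: random DAG rooted at GO:0008152 -------------------
    parents <- list()
    for (i in seq_along(terms)) {
      pool <- c(ROOT_GO, terms[seq_len(i - 1L)])
      k <- min(length(pool), sample(1:2, 1))
      parents[[terms[i]]] <- sort_c(sample(pool, k))
    }
    stanza <- function(id, name, is_a = character(0), extra = character(0)) {
      c("[Term]", paste0("id: ", id), paste0("name: ", name),
        "namespace: biological_process",
        extra,
        if (length(is_a)) paste0("is_a: ", is_a, " ! parent"),
        "")
    }
    obo <- c(
      "format-version: 1.2", "ontology: go-mini", "",
      stanza(ROOT_GO, "metabolic process"),
      unlist(lapply(seq_along(terms), function(i) {
        stanza(terms[i], paste0("mock process ", i),
               is_a = parents[[terms[i]]],
               extra = if (i == 1L) paste0("alt_id: ", alt_id))
      })),
      stanza(obsolete_id, "obsolete mock process",
             extra = "is_obsolete: true"),
      stanza(outside_id, "non-metabolic mock process"),
      "[Typedef]", "id: part_of", "name: part of"
    )
    writeLines(obo, file.path(out_dir, "go.obo"))

    # --- gene annotations -------------------------------------------
    ann <- list()
    for (g in genes) {
      k <- sample(1:2, 1)
      ann[[as.character(g)]] <- sort_c(sample(terms, min(k, length(terms))))
    }
    # make sure every term set is annotated at least once
    orphan <- setdiff(terms, unlist(ann))
    for (t in orphan) {
      g <- as.character(sample(genes, 1))
      ann[[g]] <- sort_c(union(ann[[g]], t))
    }
    g2g_rows <- unlist(lapply(names(ann), function(g) {
      sprintf("%d\t%s\t%s\tIEA\t-\tmock term\t-\tProcess",
              spec$tax_id, g, ann[[g]])
    }))
    g2g <- c(
      "#tax_id\tGeneID\tGO_ID\tEvidence\tQualifier\tGO_term\tPubMed\tCategory",
      g2g_rows,
      # excluded rows: other taxon, NOT qualifier, non-metabolic-only gene
      sprintf("10090\t555\t%s\tIEA\t-\tmock term\t-\tProcess", terms[1]),
      sprintf("%d\t%d\t%s\tIEA\tNOT\tmock term\t-\tProcess",
              spec$tax_id, genes[1], terms[1]),
      sprintf("%d\t9999\t%s\tIEA\t-\tmock term\t-\tProcess",
              spec$tax_id, outside_id)
    )
    writeLines(g2g, file.path(out_dir, "gene2go"))

    # --- gene2accession ---------------------------------------------
    n_tr <- stats::setNames(sample(1:2, length(genes), replace = TRUE),
                            genes)
    tr_tab <- list(); idx <- 0L
    for (g in genes) {
      for (j in seq_len(n_tr[[as.character(g)]])) {
        idx <- idx + 1L
        tr_tab[[idx]] <- data.frame(
          gene_id = g,
          rna = sprintf("NM_%06d", 900000L + idx),
          prot = sprintf("NP_%06d", 900000L + idx),
          stringsAsFactors = FALSE)
      }
    }
    tr_tab <- do.call(rbind, tr_tab)
    g2a_line <- function(tax, gene, rna, prot, symbol) {
      paste(c(tax, gene, "VALIDATED",
              if (rna == "-") "-" else paste0(rna, ".1"), "-",
              if (prot == "-") "-" else paste0(prot, ".1"), "-",
              "-", "-", "-", "-", "-", "-", "-", "-", symbol),
            collapse = "\t")
    }
    g2a <- c(
      paste0("#tax_id\tGeneID\tstatus\tRNA_nucleotide_accession.version\t",
             "RNA_nucleotide_gi\tprotein_accession.version\tprotein_gi\t",
             "genomic_nucleotide_accession.version\tgenomic_nucleotide_gi\t",
             "start_position_on_the_genomic_accession\t",
             "end_position_on_the_genomic_accession\torientation\tassembly\t",
             "mature_peptide_accession.version\tmature_peptide_gi\tSymbol"),
      vapply(seq_len(nrow(tr_tab)), function(i) {
        g2a_line(spec$tax_id, tr_tab$gene_id[i], tr_tab$rna[i],
                 tr_tab$prot[i], paste0("GENE", tr_tab$gene_id[i]))
      }, character(1)),
      g2a_line(spec$tax_id, genes[1], "-", "-", paste0("GENE", genes[1])),
      g2a_line(10090L, 555L, "NM_555555", "NP_555555", "Mock1"),
      g2a_line(spec$tax_id, 9999L, "NM_999999", "NP_999999", "GENE9999")
    )
    writeLines(g2a, file.path(out_dir, "gene2accession"))

    # --- enzyme.dat --------------------------------------------------
    rec <- function(id, de) c(sprintf("ID   %s", id), sprintf("DE   %s", de),
                              "//")
    enzyme <- c(
      unlist(lapply(seq_along(ecs), function(i) {
        rec(ecs[i], sprintf("Mock enzyme %d.", i))
      })),
      rec("9.9.9.1", "Transferred entry: 1.1.1.1."),
      rec("9.9.9.2", "Deleted entry.")
    )
    writeLines(enzyme, file.path(out_dir, "enzyme.dat"))

    # --- EC-protein table -------------------------------------------
    prots <- tr_tab$prot
    e2p <- list()
    for (i in seq_along(ecs)) {
      k <- min(length(prots), sample(1:2, 1))
      e2p[[i]] <- data.frame(ec = ecs[i],
                             prot = sort_c(sample(prots, k)),
                             stringsAsFactors = FALSE)
    }
    e2p <- do.call(rbind, e2p)
    writeLines(sprintf("%s\t%s.1", e2p$ec, e2p$prot),
               file.path(out_dir, "ec2protein.tsv"))

    # --- KEGG link tables -------------------------------------------
    e2r <- list()
    for (i in seq_along(ecs)) {
      k <- min(length(reactions), sample(1:2, 1))
      e2r[[i]] <- data.frame(ec = ecs[i],
                             rn = sort_c(sample(reactions, k)),
                             stringsAsFactors = FALSE)
    }
    e2r <- do.call(rbind, e2r)
    writeLines(c(sprintf("ec:%s\trn:%s", e2r$ec, e2r$rn),
                 sprintf("ec:9.9.9.1\trn:%s", reactions[1])),
               file.path(out_dir, "ec2reaction.tsv"))

    r2c <- list()
    for (i in seq_along(reactions)) {
      k <- min(length(compounds), sample(2:3, 1))
      r2c[[i]] <- data.frame(rn = reactions[i],
                             cpd = sort_c(sample(compounds, k)),
                             stringsAsFactors = FALSE)
    }
    r2c <- do.call(rbind, r2c)
    writeLines(c(sprintf("rn:%s\tcpd:%s", r2c$rn, r2c$cpd),
                 sprintf("rn:%s\tgl:G00001", reactions[1])),
               file.path(out_dir, "reaction2compound.tsv"))

    # --- truth: direct composition of the decided tuples ------------
    gene_go <- do.call(rbind, lapply(names(ann), function(g) {
      data.frame(gene_id = as.integer(g), term_id = ann[[g]],
                 stringsAsFactors = FALSE)
    }))
    gene_go <- order_df(unique(gene_go))
    gene_prot <- tr_tab[, c("gene_id", "prot")]
    prot_ec <- e2p
    ec_rn <- e2r[e2r$ec %in% ecs, , drop = FALSE]
    rn_cpd <- r2c
    kept_rn <- sort_c(intersect(unique(ec_rn$rn), unique(rn_cpd$rn)))
    ec_rn <- ec_rn[ec_rn$rn %in% kept_rn, , drop = FALSE]
    rn_cpd <- rn_cpd[rn_cpd$rn %in% kept_rn, , drop = FALSE]

    gene_ec <- unique(merge(gene_prot, prot_ec, by = "prot")[
      , c("gene_id", "ec")])
    gene_rn <- unique(merge(gene_ec, ec_rn, by = "ec")[, c("gene_id", "rn")])
    gene_cpd <- unique(merge(gene_rn, rn_cpd, by = "rn")[
      , c("gene_id", "cpd")])
    term_cpd <- unique(merge(gene_go, gene_cpd, by = "gene_id")[
      , c("term_id", "cpd")])
    t2c <- lapply(split(term_cpd$cpd, term_cpd$term_id),
                  function(x) sort_c(unique(x)))
    t2g <- lapply(split(gene_go$gene_id, gene_go$term_id),
                  function(x) sort(unique(x)))

    truth <- list(
      terms = I(sort_c(c(ROOT_GO, terms))),
      genes = I(sort(unique(gene_go$gene_id))),
      transcripts = I(sort_c(unique(tr_tab$rna))),
      proteins = I(sort_c(unique(tr_tab$prot))),
      ecs = I(sort_c(unique(prot_ec$ec))),
      reactions = I(kept_rn),
      compounds = I(sort_c(unique(rn_cpd$cpd))),
      edges = list(
        gene_go = gene_go,
        gene_transcript = order_df(unique(stats::setNames(
          tr_tab[, c("gene_id", "rna")],
          c("gene_id", "rna_accession")))),
        transcript_protein = order_df(unique(stats::setNames(
          tr_tab[, c("rna", "prot")],
          c("rna_accession", "protein_accession")))),
        protein_ec = order_df(unique(stats::setNames(
          prot_ec[, c("prot", "ec")],
          c("protein_accession", "ec_number")))),
        ec_reaction = order_df(unique(stats::setNames(
          ec_rn[, c("ec", "rn")], c("ec_number", "reaction_id")))),
        reaction_compound = order_df(unique(stats::setNames(
          rn_cpd[, c("rn", "cpd")], c("reaction_id", "compound_id"))))
      ),
      term_to_compounds = lapply(t2c[sort_c(names(t2c))], I),
      term_to_genes = lapply(t2g[sort_c(names(t2g))], I),
      background_n = length(unique(term_cpd$cpd))
    )
    truth_path <- file.path(out_dir, "truth.json")
    writeLines(as.character(jsonlite::toJSON(truth, auto_unbox = TRUE,
                                             digits = NA)),
               truth_path)

    src <- find_sources(out_dir)
    attr(src, "truth") <- truth_path
    src
  })
}

#' Read a fixture truth file
#'
#' @param path Path to a `truth.json` written by
#'   [generate_mock_sources()].
#' @return The truth description as a list.
#' @export
read_truth <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  doc$term_to_compounds <- lapply(doc$term_to_compounds, chr0)
  doc$term_to_genes <- lapply(doc$term_to_genes,
                              function(x) as.integer(unlist(x)))
  doc
}

#' Synthetic knowledgebase reproducing the published worked example
#'
#' Builds an in-memory knowledgebase whose statistical frame matches
#' the published nucleoside-salvage example: one GO term (GO:0043174)
#' with exactly 61 linked compounds inside a GO-linked universe of
#' 2,212 compounds, annotated with 4 genes. All identifiers are
#' synthetic; only the counts are meaningful. Use
#' [worked_example_input()] for the matching 62-compound input list of
#' which 13 overlap the term.
#'
#' @return A `metago_kb` object (synthetic).
#' @export
worked_example_kb <- function() {
  universe <- sprintf("C%05d", seq_len(2212L))
  term_set <- universe[seq_len(61L)]
  term <- "GO:0043174"
  terms <- list(
    `GO:0008152` = list(term_id = ROOT_GO, name = "metabolic process",
                        namespace = "biological_process",
                        parents = character(0), alt_ids = character(0),
                        obsolete = FALSE),
    `GO:0043174` = list(term_id = term, name = "nucleoside salvage",
                        namespace = "biological_process",
                        parents = ROOT_GO, alt_ids = character(0),
                        obsolete = FALSE)
  )
  genes <- 101:110
  empty_edges <- list(
    gene_go = data.frame(gene_id = integer(0), term_id = character(0),
                         stringsAsFactors = FALSE),
    gene_transcript = data.frame(gene_id = integer(0),
                                 rna_accession = character(0),
                                 stringsAsFactors = FALSE),
    transcript_protein = data.frame(rna_accession = character(0),
                                    protein_accession = character(0),
                                    stringsAsFactors = FALSE),
    protein_ec = data.frame(protein_accession = character(0),
                            ec_number = character(0),
                            stringsAsFactors = FALSE),
    ec_reaction = data.frame(ec_number = character(0),
                             reaction_id = character(0),
                             stringsAsFactors = FALSE),
    reaction_compound = data.frame(reaction_id = character(0),
                                   compound_id = character(0),
                                   stringsAsFactors = FALSE)
  )
  manifest <- list(format = "metago-kb-json", format_version = 1L,
                   tool = "metago",
                   tool_version = as.character(
                     utils::packageVersion("metago")),
                   tax_id = 9606L, root_id = ROOT_GO, propagate = FALSE,
                   unfiltered_ec = FALSE,
                   accessed = "synthetic-worked-example")
  structure(list(
    terms = terms,
    alt_to_primary = character(0),
    genes = data.frame(gene_id = genes,
                       symbol = sprintf("SYN%d", genes),
                       tax_id = 9606L, stringsAsFactors = FALSE),
    transcripts = character(0),
    proteins = character(0),
    enzymes = data.frame(ec_number = character(0),
                         description = character(0),
                         status = character(0), stringsAsFactors = FALSE),
    reactions = character(0),
    compounds = data.frame(compound_id = universe, name = NA_character_,
                           stringsAsFactors = FALSE),
    edges = empty_edges,
    term_to_compounds = list(`GO:0008152` = universe,
                             `GO:0043174` = term_set),
    term_to_genes = list(`GO:0008152` = genes, `GO:0043174` = 101:104),
    universe = universe,
    background_n = length(universe),
    tax_id = 9606L, root_id = ROOT_GO, propagate = FALSE,
    unfiltered_ec = FALSE,
    manifest = manifest
  ), class = "metago_kb")
}

#' Input list matching the worked-example knowledgebase
#'
#' 62 synthetic KEGG compound accessions, all inside the
#' [worked_example_kb()] universe, of which exactly 13 fall in the
#' nucleoside-salvage term's 61-compound set — the published example's
#' x = 13, y = 61, b = 62 frame.
#'
#' @return Character vector of 62 compound accessions.
#' @export
worked_example_input <- function() {
  c(sprintf("C%05d", seq_len(13L)),            # inside the term set
    sprintf("C%05d", 1000L + seq_len(49L)))    # elsewhere in the universe
}
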