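# Hand-built miniature source bundle tracing a known two-gene graph:
#   gene 1001 (GO:1000001) -> EC 1.1.1.1 -> R00001 -> {C00001, C00002}
#   gene 1002 (GO:1000002) -> EC 2.2.2.2 -> R00002 -> {C00002, C00003}
# plus decoys: a transferred EC with reaction links (must be ignored),
# a gene annotated only outside the metabolic sub-ontology (must be
# excluded), an obsolete term, an alt_id, a NOT-qualified row and a
# mouse row.
write_two_gene_sources <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0008152", "name: metabolic process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:1000001", "name: process A",
    "namespace: biological_process", "alt_id: GO:0200001",
    "is_a: GO:0008152 ! metabolic process", "",
    "[Term]", "id: GO:1000002", "name: process B",
    "namespace: biological_process",
    "is_a: GO:0008152 ! metabolic process", "",
    "[Term]", "id: GO:0900001", "name: gone",
    "namespace: biological_process", "is_obsolete: true", "",
    "[Term]", "id: GO:0990001", "name: unrelated process",
    "namespace: biological_process", ""
  ), file.path(dir, "go.obo"))

  writeLines(c(
    "#tax_id\tGeneID\tGO_ID\tEvidence\tQualifier\tGO_term\tPubMed\tCategory",
    "9606\t1001\tGO:1000001\tIEA\t-\tprocess A\t-\tProcess",
    "9606\t1002\tGO:1000002\tIEA\t-\tprocess B\t-\tProcess",
    "9606\t1003\tGO:0990001\tIEA\t-\tunrelated\t-\tProcess",
    "9606\t1001\tGO:1000002\tIEA\tNOT\tprocess B\t-\tProcess",
    "10090\t555\tGO:1000001\tIEA\t-\tprocess A\t-\tProcess"
  ), file.path(dir, "gene2go"))

  row16 <- function(tax, gene, rna, prot, sym) {
    paste(c(tax, gene, "VALIDATED", rna, "-", prot, "-",
            rep("-", 8), sym), collapse = "\t")
  }
  writeLines(c(
    paste0("#tax_id\tGeneID\tstatus\tRNA_nucleotide_accession.version\t",
           "RNA_gi\tprotein_accession.version\tprotein_gi\tg\tgi\ts\te\t",
           "o\ta\tm\tmi\tSymbol"),
    row16(9606, 1001, "NM_000001.3", "NP_000001.1", "GENEA"),
    row16(9606, 1002, "NM_000002.2", "NP_000002.2", "GENEB"),
    row16(9606, 1003, "NM_000003.1", "NP_000003.1", "GENEC"),
    row16(9606, 1001, "-", "-", "GENEA")
  ), file.path(dir, "gene2accession"))

  writeLines(c(
    "ID   1.1.1.1", "DE   Alcohol dehydrogenase.", "//",
    "ID   2.2.2.2", "DE   Mock transferase.", "//",
    "ID   9.9.9.1", "DE   Transferred entry: 1.1.1.1.", "//",
    "ID   9.9.9.2", "DE   Deleted entry.", "//"
  ), file.path(dir, "enzyme.dat"))

  writeLines(c(
    "1.1.1.1\tNP_000001.1",
    "2.2.2.2\tNP_000002",
    "1.1.1.1\tNP_000003"   # protein of the excluded gene 1003
  ), file.path(dir, "ec2protein.tsv"))

  writeLines(c(
    "ec:1.1.1.1\trn:R00001",
    "ec:2.2.2.2\trn:R00002",
    "ec:9.9.9.1\trn:R00099"   # transferred EC: links must be ignored
  ), file.path(dir, "ec2reaction.tsv"))

  writeLines(c(
    "rn:R00001\tcpd:C00001",
    "rn:R00001\tcpd:C00002",
    "rn:R00002\tcpd:C00002",
    "rn:R00002\tcpd:C00003",
    "rn:R00099\tcpd:C00099"
  ), file.path(dir, "reaction2compound.tsv"))

  metago::source_bundle(
    obo = file.path(dir, "go.obo"),
    gene2go = file.path(dir, "gene2go"),
    gene2accession = file.path(dir, "gene2accession"),
    enzyme_dat = file.path(dir, "enzyme.dat"),
    ec2reaction = file.path(dir, "ec2reaction.tsv"),
    reaction2compound = file.path(dir, "reaction2compound.tsv"),
    ec2protein = file.path(dir, "ec2protein.tsv")
  )
}

build_two_gene_kb <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  metago::build_knowledgebase(write_two_gene_sources(dir))
}

# In-memory KB with two terms over a six-compound universe:
#   A: {C00001, C00002, C00003}, B: {C00003, C00004, C00005, C00006}
small_ora_kb <- function(gene_counts = c(A = 3L, B = 3L)) {
  kb <- metago::worked_example_kb()
  universe <- sprintf("C%05d", 1:6)
  sets <- list(
    `GO:1000001` = universe[1:3],
    `GO:1000002` = universe[3:6]
  )
  kb$terms <- list(
    `GO:0008152` = list(term_id = "GO:0008152", name = "metabolic process",
                        namespace = "biological_process",
                        parents = character(0), alt_ids = character(0),
                        obsolete = FALSE),
    `GO:1000001` = list(term_id = "GO:1000001", name = "process A",
                        namespace = "biological_process",
                        parents = "GO:0008152", alt_ids = character(0),
                        obsolete = FALSE),
    `GO:1000002` = list(term_id = "GO:1000002", name = "process B",
                        namespace = "biological_process",
                        parents = "GO:0008152", alt_ids = character(0),
                        obsolete = FALSE)
  )
  kb$term_to_compounds <- sets
  kb$term_to_genes <- list(
    `GO:1000001` = seq_len(gene_counts[["A"]]) + 100L,
    `GO:1000002` = seq_len(gene_counts[["B"]]) + 200L
  )
  kb$compounds <- data.frame(compound_id = universe, name = NA_character_,
                             stringsAsFactors = FALSE)
  kb$universe <- universe
  kb$background_n <- length(universe)
  kb
}
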