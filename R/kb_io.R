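# Knowledgebase archive: one JSON document (gzip-compressed when the
# path ends in .gz) with fully sorted keys and fixed column order, so
# that rebuilding from identical inputs gives byte-identical archives.

serialize_kb <- function(kb) {
  stopifnot(inherits(kb, "metago_kb"))
  term_list <- lapply(kb$terms[sort_c(names(kb$terms))], function(t) {
    list(term_id = t$term_id, name = t$name, namespace = t$namespace,
         parents = I(t$parents), alt_ids = I(t$alt_ids),
         obsolete = t$obsolete)
  })
  alt <- kb$alt_to_primary[sort_c(names(kb$alt_to_primary))]
  doc <- list(
    manifest = kb$manifest,
    terms = term_list,
    alt_to_primary = as.list(alt),
    genes = kb$genes,
    transcripts = I(kb$transcripts),
    proteins = I(kb$proteins),
    enzymes = kb$enzymes,
    reactions = I(kb$reactions),
    compounds = kb$compounds,
    edges = kb$edges,
    term_to_compounds = lapply(kb$term_to_compounds, I),
    term_to_genes = lapply(kb$term_to_genes, I),
    universe = I(kb$universe),
    background_n = kb$background_n
  )
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                na = "null", null = "null"))
}

#' Write a knowledgebase archive
#'
#' Serializes a knowledgebase to a single JSON document; paths ending in
#' `.gz` are gzip-compressed. Serialization is deterministic: the same
#' knowledgebase always produces the same bytes.
#'
#' @param kb A `metago_kb` object.
#' @param path Output path (`.json` or `.json.gz`).
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  txt <- serialize_kb(kb)
  con <- if (endsWith(path, ".gz")) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(txt), con)
  invisible(path)
}

chr0 <- function(x) {
  if (is.null(x) || !length(x)) character(0) else as.character(unlist(x))
}

as_df <- function(x, cols, int_cols = character(0)) {
  if (is.null(x) || (is.list(x) && !length(x)) ||
      (is.data.frame(x) && !nrow(x))) {
    out <- lapply(cols, function(cc) {
      if (cc %in% int_cols) integer(0) else character(0)
    })
    names(out) <- cols
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  df <- as.data.frame(x, stringsAsFactors = FALSE)[, cols, drop = FALSE]
  for (cc in int_cols) df[[cc]] <- as.integer(df[[cc]])
  rownames(df) <- NULL
  df
}

#' Read a knowledgebase archive
#'
#' @param path Path written by [write_kb()].
#' @return A `metago_kb` object.
#' @export
read_kb <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  doc <- jsonlite::fromJSON(paste(readLines(con, warn = FALSE),
                                  collapse = "\n"),
                            simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  if (!identical(doc$manifest$format, "metago-kb-json")) {
    format_error("'%s' is not a metago knowledgebase archive", path)
  }
  terms <- lapply(doc$terms, function(t) {
    list(term_id = t$term_id, name = t$name %||% "",
         namespace = t$namespace %||% "",
         parents = chr0(t$parents), alt_ids = chr0(t$alt_ids),
         obsolete = isTRUE(t$obsolete))
  })
  alt <- unlist(doc$alt_to_primary) %||% character(0)
  if (!length(alt)) alt <- character(0)
  manifest <- doc$manifest
  manifest$format_version <- as.integer(manifest$format_version)
  manifest$tax_id <- as.integer(manifest$tax_id)
  structure(list(
    terms = terms,
    alt_to_primary = alt,
    genes = as_df(doc$genes, c("gene_id", "symbol", "tax_id"),
                  int_cols = c("gene_id", "tax_id")),
    transcripts = chr0(doc$transcripts),
    proteins = chr0(doc$proteins),
    enzymes = as_df(doc$enzymes, c("ec_number", "description", "status")),
    reactions = chr0(doc$reactions),
    compounds = as_df(doc$compounds, c("compound_id", "name")),
    edges = list(
      gene_go = as_df(doc$edges$gene_go, c("gene_id", "term_id"),
                      int_cols = "gene_id"),
      gene_transcript = as_df(doc$edges$gene_transcript,
                              c("gene_id", "rna_accession"),
                              int_cols = "gene_id"),
      transcript_protein = as_df(doc$edges$transcript_protein,
                                 c("rna_accession", "protein_accession")),
      protein_ec = as_df(doc$edges$protein_ec,
                         c("protein_accession", "ec_number")),
      ec_reaction = as_df(doc$edges$ec_reaction,
                          c("ec_number", "reaction_id")),
      reaction_compound = as_df(doc$edges$reaction_compound,
                                c("reaction_id", "compound_id"))
    ),
    term_to_compounds = lapply(doc$term_to_compounds, chr0),
    term_to_genes = lapply(doc$term_to_genes,
                           function(x) as.integer(unlist(x))),
    universe = chr0(doc$universe),
    background_n = as.integer(doc$background_n),
    tax_id = manifest$tax_id,
    root_id = manifest$root_id,
    propagate = isTRUE(manifest$propagate),
    unfiltered_ec = isTRUE(manifest$unfiltered_ec),
    manifest = manifest
  ), class = "metago_kb")
}
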