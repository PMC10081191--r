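# Parsers for the tabular and flat-file knowledgebase sources. All of
# them accept plain or gzip-compressed files and report per-line or
# per-record positions on malformed input.

split_tsv <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Parse NCBI gene2go annotations
#'
#' Reads the NCBI `gene2go` tab-delimited file (8 columns: tax_id,
#' GeneID, GO_ID, Evidence, Qualifier, GO_term, PubMed, Category) and
#' returns the distinct gene-to-GO-term annotation pairs for one taxon.
#' Rows whose Qualifier contains a NOT qualifier (negated annotations,
#' e.g. `NOT` or `NOT|contributes_to`) are excluded.
#'
#' @param path Path to a gene2go file (plain or gzipped).
#' @param tax_id NCBI taxonomy id to keep (default 9606, human).
#' @return data.frame with columns `gene_id` (integer) and `term_id`,
#'   one row per distinct annotation.
#' @export
parse_gene2go <- function(path, tax_id = 9606L) {
  lines <- read_lines_any(path)
  data_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  fields <- split_tsv(lines[data_idx])
  ncols <- lengths(fields)
  bad <- which(ncols != 8L)
  if (length(bad)) {
    format_error("gene2go line %d has %d columns, expected 8",
                 data_idx[bad[1]], ncols[bad[1]])
  }
  m <- matrix(unlist(fields), ncol = 8L, byrow = TRUE)
  keep <- m[, 1] == as.character(tax_id) &
    !vapply(strsplit(m[, 5], "|", fixed = TRUE),
            function(q) any(q == "NOT"), logical(1))
  out <- unique(data.frame(
    gene_id = as.integer(m[keep, 2]),
    term_id = m[keep, 3],
    stringsAsFactors = FALSE
  ))
  out[order(out$gene_id, out$term_id, method = "radix"), , drop = FALSE]
}

#' Parse NCBI gene2accession
#'
#' Reads the NCBI `gene2accession` tab-delimited file and returns, for
#' one taxon, the (gene, transcript accession, protein accession)
#' triples. Accession version suffixes are stripped so joins against
#' other sources are version-independent; the `-` placeholder becomes
#' `NA`, and rows with placeholders in both accession columns are
#' dropped. The gene symbol (column 16) is carried along when present.
#'
#' @param path Path to a gene2accession file (plain or gzipped).
#' @param tax_id NCBI taxonomy id to keep.
#' @return data.frame with columns `gene_id`, `rna_accession`,
#'   `protein_accession`, `symbol` (NA when the file has fewer than 16
#'   columns), one row per distinct triple.
#' @export
parse_gene2accession <- function(path, tax_id = 9606L) {
  lines <- read_lines_any(path)
  data_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  fields <- split_tsv(lines[data_idx])
  ncols <- lengths(fields)
  bad <- which(ncols < 7L)
  if (length(bad)) {
    format_error("gene2accession line %d has %d columns, expected >= 7",
                 data_idx[bad[1]], ncols[bad[1]])
  }
  pick <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[i] else "-"
  }, character(1))
  tax <- pick(1L)
  rna <- strip_version(pick(4L))
  prot <- strip_version(pick(6L))
  keep <- tax == as.character(tax_id) & !(rna == "-" & prot == "-")
  out <- unique(data.frame(
    gene_id = as.integer(pick(2L)[keep]),
    rna_accession = ifelse(rna[keep] == "-", NA_character_, rna[keep]),
    protein_accession = ifelse(prot[keep] == "-", NA_character_, prot[keep]),
    symbol = ifelse(pick(16L)[keep] == "-", NA_character_, pick(16L)[keep]),
    stringsAsFactors = FALSE
  ))
  out[order(out$gene_id, out$rna_accession, out$protein_accession,
            method = "radix", na.last = TRUE), , drop = FALSE]
}

#' Parse Expasy enzyme.dat records
#'
#' Reads the Expasy ENZYME flat file (records separated by `//`, line
#' types ID/DE/...) and classifies every EC entry as active,
#' transferred (DE begins "Transferred entry") or deleted (DE begins
#' "Deleted entry"). Only active entries may carry reaction links
#' downstream. Entries whose ID contains provisional wildcard fields
#' (e.g. `1.1.1.n1`) are dropped with a warning, since the knowledgebase
#' joins on fully specified four-field EC numbers.
#'
#' @param path Path to an enzyme.dat file (plain or gzipped).
#' @return data.frame with columns `ec_number`, `description`, `status`.
#' @export
parse_enzyme_dat <- function(path) {
  lines <- read_lines_any(path)
  rec_end <- which(lines == "//")
  starts <- c(1L, head(rec_end, -1L) + 1L)
  out <- list()
  for (k in seq_along(rec_end)) {
    body <- lines[starts[k]:(rec_end[k] - 1L)]
    body <- body[nzchar(body)]
    if (!length(body)) next
    types <- substring(body, 1L, 2L)
    # the file's preamble block (release notes) carries only CC lines
    if (all(types %in% c("CC", "  "))) next
    id_lines <- body[types == "ID"]
    if (!length(id_lines)) {
      format_error("enzyme.dat record %d lacks an ID line", k)
    }
    ec <- trimws(substring(id_lines[1], 3L))
    de <- paste(trimws(substring(body[types == "DE"], 3L)), collapse = " ")
    status <- if (startsWith(de, "Transferred entry")) "transferred"
              else if (startsWith(de, "Deleted entry")) "deleted"
              else "active"
    if (status == "active" && !is_ec_number(ec)) {
      warning(sprintf("dropping enzyme entry with provisional EC '%s'", ec),
              call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      ec_number = ec, description = de, status = status,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out) %||%
    data.frame(ec_number = character(0), description = character(0),
               status = character(0), stringsAsFactors = FALSE)
  res[order(res$ec_number, method = "radix"), , drop = FALSE]
}

#' Parse a KEGG REST link table
#'
#' Reads a two-column tab-delimited table in the KEGG REST `link`
#' dialect, where identifiers carry database prefixes (`ec:1.1.1.1`,
#' `rn:R00623`, `cpd:C00001`). Prefixes are stripped; glycan (`gl:`)
#' targets are dropped (they are not KEGG compounds); rows carrying any
#' other unexpected prefix are dropped with a warning.
#'
#' @param path Path to the link table (plain or gzipped).
#' @param from_prefix Expected prefix of column 1 (e.g. `"ec"`).
#' @param to_prefix Expected prefix of column 2 (e.g. `"rn"`).
#' @return data.frame with columns `from_id`, `to_id`, prefixes removed.
#' @export
parse_kegg_link <- function(path, from_prefix, to_prefix) {
  lines <- read_lines_any(path)
  data_idx <- which(nzchar(lines))
  fields <- split_tsv(lines[data_idx])
  ncols <- lengths(fields)
  bad <- which(ncols != 2L)
  if (length(bad)) {
    format_error("KEGG link line %d has %d columns, expected 2",
                 data_idx[bad[1]], ncols[bad[1]])
  }
  m <- matrix(unlist(fields), ncol = 2L, byrow = TRUE)
  pfx <- function(x) sub(":.*$", "", x)
  from_ok <- pfx(m[, 1]) == from_prefix
  to_ok <- pfx(m[, 2]) == to_prefix
  glycan <- pfx(m[, 2]) == "gl"
  unexpected <- !(from_ok & (to_ok | glycan))
  if (any(unexpected)) {
    warning(sprintf(
      "dropping %d KEGG link row(s) with unexpected prefixes (e.g. '%s')",
      sum(unexpected), paste(m[which(unexpected)[1], ], collapse = "\t")),
      call. = FALSE)
  }
  keep <- from_ok & to_ok
  out <- unique(data.frame(
    from_id = sub("^[^:]*:", "", m[keep, 1]),
    to_id = sub("^[^:]*:", "", m[keep, 2]),
    stringsAsFactors = FALSE
  ))
  out[order(out$from_id, out$to_id, method = "radix"), , drop = FALSE]
}

# Pre-fetched EC-to-protein table: two tab-separated columns, EC number
# (optionally "ec:"-prefixed) and NCBI protein accession (version
# tolerated). Stands in for live NCBI eutils EC<->protein retrieval.
parse_ec2protein <- function(path) {
  lines <- read_lines_any(path)
  data_idx <- which(nzchar(lines) & !startsWith(lines, "#"))
  fields <- split_tsv(lines[data_idx])
  ncols <- lengths(fields)
  bad <- which(ncols != 2L)
  if (length(bad)) {
    format_error("ec2protein line %d has %d columns, expected 2",
                 data_idx[bad[1]], ncols[bad[1]])
  }
  m <- matrix(unlist(fields), ncol = 2L, byrow = TRUE)
  out <- unique(data.frame(
    ec_number = sub("^ec:", "", m[, 1]),
    protein_accession = strip_version(m[, 2]),
    stringsAsFactors = FALSE
  ))
  out[order(out$ec_number, out$protein_accession, method = "radix"), ,
      drop = FALSE]
}
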