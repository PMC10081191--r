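#' Map input compound identifiers onto the knowledgebase universe
#'
#' Tests each KEGG compound identifier of the input list for membership
#' in the knowledgebase's GO-linked compound universe. Duplicated input
#' identifiers are collapsed with a warning, and identifiers that are
#' not syntactically valid C-numbers are reported with a warning (they
#' count as unmapped, not as errors). The mapped size `b` is the number
#' of draws in the downstream hypergeometric test.
#'
#' @param kb A `metago_kb` object.
#' @param input_ids Character vector of KEGG compound accessions
#'   (`C` + 5 digits), e.g. the significant compounds of a study.
#' @return A list of class `metago_mapped` with `found` (sorted
#'   character vector), `missing` (in input order), `invalid`, and
#'   `b = length(found)`.
#' @export
map_input_ids <- function(kb, input_ids) {
  stopifnot(inherits(kb, "metago_kb"))
  ids <- trimws(as.character(input_ids))
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) {
    warning(sprintf("%d duplicated input identifier(s) collapsed",
                    sum(duplicated(ids))), call. = FALSE)
    ids <- ids[!duplicated(ids)]
  }
  valid <- is_compound_id(ids)
  if (any(!valid)) {
    warning(sprintf(
      "%d input identifier(s) are not valid KEGG C-numbers (e.g. '%s')",
      sum(!valid), ids[!valid][1]), call. = FALSE)
  }
  found <- ids[valid & ids %in% kb$universe]
  if (!length(found)) {
    analysis_error("no input compounds mapped to the knowledgebase universe")
  }
  structure(list(
    found = sort_c(found),
    missing = ids[!(ids %in% found)],
    invalid = ids[!valid],
    b = length(found)
  ), class = "metago_mapped")
}

#' Upper-tail hypergeometric probability
#'
#' Probability of drawing at least `x` successes in `b` draws without
#' replacement from an urn with `y` successes and `a` failures:
#' \eqn{P[X \ge x]} for \eqn{X \sim} Hypergeometric(`y`, `a`, `b`).
#' Computed through the survival form of [stats::phyper()]
#' (`phyper(x - 1, y, a, b, lower.tail = FALSE)`), which is evaluated
#' in a numerically stable way for extreme tails.
#'
#' In the enrichment test, `x` is the overlap between the mapped input
#' list and a GO term's compound set, `y` the term's compound-set size,
#' `a` the rest of the background universe, and `b` the mapped input
#' size.
#'
#' @param x Minimum number of successes (non-negative integer,
#'   `x <= min(y, b)`).
#' @param y Number of successes in the population.
#' @param a Number of failures in the population.
#' @param b Number of draws (`b <= y + a`).
#' @return Probability in \[0, 1\].
#' @examples
#' hypergeom_upper_tail(13, 61, 2151, 62)
#' @export
hypergeom_upper_tail <- function(x, y, a, b) {
  for (v in list(x = x, y = y, a = a, b = b)) {
    if (length(v) != 1L || is.na(v) || v < 0 || v != trunc(v)) {
      stop_with("metago_domain_error",
                "x, y, a, b must be single non-negative integers")
    }
  }
  if (x > min(y, b) || b > y + a) {
    stop_with("metago_domain_error",
              "require x <= min(y, b) and b <= y + a (got x=%g y=%g a=%g b=%g)",
              x, y, a, b)
  }
  stats::phyper(x - 1, m = y, n = a, k = b, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment
#' \eqn{q_{(i)} = \min_{j \ge i} (m \, p_{(j)} / j)}, capped at 1 and
#' returned in input order, with `m = length(p)`. Delegates to
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_with("metago_domain_error", "p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Relevance filters for an enrichment result
#'
#' A GO term passes when (1) the overlap `x` is at least `min_overlap`,
#' (2) the term has at least `min_genes` annotated genes, and (3) the
#' overlap exceeds `min_overlap_fraction` of the term's compound-set
#' size `y` (strictly greater). The defaults (3, 3, 0.05) narrow the
#' report to terms with enough biological support.
#'
#' @param x Overlap count.
#' @param y Term compound-set size.
#' @param gene_count Number of genes annotated to the term.
#' @param min_overlap,min_genes,min_overlap_fraction Filter thresholds.
#' @return Logical (vectorized over `x`, `y`, `gene_count`).
#' @export
apply_filters <- function(x, y, gene_count, min_overlap = 3L,
                          min_genes = 3L, min_overlap_fraction = 0.05) {
  x >= min_overlap & gene_count >= min_genes & x > min_overlap_fraction * y
}

validate_query <- function(alpha, min_overlap, min_genes,
                           min_overlap_fraction) {
  if (!(alpha > 0 && alpha < 1)) {
    stop_with("metago_domain_error", "alpha must be in (0, 1)")
  }
  if (min_overlap < 1) {
    stop_with("metago_domain_error", "min_overlap must be >= 1")
  }
  if (!(min_overlap_fraction >= 0 && min_overlap_fraction < 1)) {
    stop_with("metago_domain_error",
              "min_overlap_fraction must be in [0, 1)")
  }
  invisible(TRUE)
}

#' Run GO-term over-representation analysis on a compound list
#'
#' Maps the input KEGG compound list onto the knowledgebase universe and
#' tests every GO term with at least one linked compound for
#' over-representation with the upper-tail hypergeometric test: for a
#' term with compound set of size `y`, overlap `x` with the mapped
#' input of size `b`, and `a = background_n - y` remaining background
#' compounds, the p-value is \eqn{P[X \ge x]}
#' (see [hypergeom_upper_tail()]).
#'
#' Relevance filters (see [apply_filters()]) are applied before FDR
#' adjustment, so the Benjamini-Hochberg `m` is the number of
#' filter-passing terms; set `fdr_all_terms = TRUE` to adjust across all
#' tested terms instead (sensitivity analysis). Results are sorted by
#' p-value, ties broken by term accession, so reports are deterministic.
#'
#' @param kb A `metago_kb` object.
#' @param input_ids Character vector of KEGG compound accessions.
#' @param alpha FDR significance threshold carried into the report
#'   (default 0.05).
#' @param min_overlap,min_genes,min_overlap_fraction Filter thresholds
#'   (defaults 3, 3, 0.05).
#' @param fdr_all_terms Adjust over all tested terms instead of the
#'   filter-passing subset (default `FALSE`).
#' @return An object of class `metago_ora`: list with `results` (one
#'   data.frame row per tested term: `term_id`, `term_name`, `x`, `y`,
#'   `a`, `b`, `gene_count`, `p_value`, `q_value`, `passed_filters`,
#'   list-column `overlap_compounds`), `query`, `mapped`, `kb_version`.
#' @export
run_ora <- function(kb, input_ids, alpha = 0.05, min_overlap = 3L,
                    min_genes = 3L, min_overlap_fraction = 0.05,
                    fdr_all_terms = FALSE) {
  stopifnot(inherits(kb, "metago_kb"))
  validate_query(alpha, min_overlap, min_genes, min_overlap_fraction)
  mapped <- map_input_ids(kb, input_ids)
  found <- mapped$found
  b <- mapped$b
  n_bg <- kb$background_n

  term_ids <- names(kb$term_to_compounds)
  overlap <- lapply(kb$term_to_compounds,
                    function(set) sort_c(intersect(found, set)))
  x <- lengths(overlap)
  y <- lengths(kb$term_to_compounds)
  a <- n_bg - y
  gene_count <- vapply(term_ids, function(t) {
    length(kb$term_to_genes[[t]])
  }, integer(1))
  p <- vapply(seq_along(term_ids), function(i) {
    hypergeom_upper_tail(x[i], y[i], a[i], b)
  }, numeric(1))
  passed <- apply_filters(x, y, gene_count, min_overlap, min_genes,
                          min_overlap_fraction)

  q <- rep(NA_real_, length(p))
  if (fdr_all_terms) {
    q <- bh_fdr(p)
  } else if (any(passed)) {
    q[passed] <- bh_fdr(p[passed])
  }

  res <- data.frame(
    term_id = term_ids,
    term_name = vapply(term_ids, function(t) kb$terms[[t]]$name %||% "",
                       character(1)),
    x = as.integer(x), y = as.integer(y), a = as.integer(a),
    b = as.integer(b),
    gene_count = as.integer(gene_count),
    p_value = p, q_value = q,
    passed_filters = passed,
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$overlap_compounds <- unname(overlap)
  ord <- order(res$p_value, res$term_id, method = "radix")
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL

  structure(list(
    results = res,
    query = list(alpha = alpha, min_overlap = min_overlap,
                 min_genes = min_genes,
                 min_overlap_fraction = min_overlap_fraction,
                 fdr_all_terms = fdr_all_terms,
                 input_ids = as.character(input_ids)),
    mapped = mapped,
    kb_version = kb_version(kb)
  ), class = "metago_ora")
}

#' Impact table of an enrichment report
#'
#' One record per filter-passing term, pairing the term's compound-set
#' size with \eqn{-\log_{10}(p)} (p floored at 1e-300 to avoid
#' infinities). Plotting set size against \eqn{-\log_{10}(p)} shows how
#' specific each over-represented process is: small sets with large
#' \eqn{-\log_{10}(p)} mark the most specific processes.
#'
#' @param report A `metago_ora` report.
#' @return data.frame with columns `term_id`, `term_name`, `set_size`,
#'   `neg_log10_p`, `q_value`, `passed_filters`.
#' @export
impact_table <- function(report) {
  stopifnot(inherits(report, "metago_ora"))
  res <- report$results[report$results$passed_filters, , drop = FALSE]
  data.frame(
    term_id = res$term_id,
    term_name = res$term_name,
    set_size = res$y,
    neg_log10_p = -log10(pmax(res$p_value, 1e-300)),
    q_value = res$q_value,
    passed_filters = res$passed_filters,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Flatten an enrichment report for export
#'
#' @param report A `metago_ora` report.
#' @return data.frame identical to `report$results` but with
#'   `overlap_compounds` semicolon-joined into a character column.
#' @export
ora_table <- function(report) {
  stopifnot(inherits(report, "metago_ora"))
  res <- report$results
  res$overlap_compounds <- vapply(res$overlap_compounds, paste,
                                  character(1), collapse = ";")
  res
}

#' Apply an identifier-mapping table to an input list
#'
#' Translates arbitrary upstream identifiers (for example PubChem CIDs)
#' into KEGG C-numbers through a user-supplied two-column table before
#' analysis. Identifiers absent from the table pass through unchanged
#' (they may already be C-numbers).
#'
#' @param input_ids Character vector of identifiers.
#' @param map data.frame whose first column holds source identifiers
#'   and second column KEGG compound accessions, or a path to a
#'   two-column TSV.
#' @return Character vector of translated identifiers, duplicates
#'   removed, input order preserved.
#' @export
apply_id_map <- function(input_ids, map) {
  if (is.character(map) && length(map) == 1L) {
    map <- utils::read.delim(map, header = FALSE,
                             colClasses = "character",
                             comment.char = "#")
  }
  if (ncol(map) < 2L) {
    format_error("identifier map must have two columns")
  }
  lut <- as.character(map[[2]])
  names(lut) <- as.character(map[[1]])
  ids <- as.character(input_ids)
  hit <- ids %in% names(lut)
  ids[hit] <- unname(lut[ids[hit]])
  ids[!duplicated(ids)]
}

#' @export
print.metago_ora <- function(x, ...) {
  cat("<metago ORA report>", x$kb_version, "\n")
  cat(sprintf("  mapped %d / %d input compounds; %d terms tested, %d pass filters, %d with q < %g\n",
              x$mapped$b, x$mapped$b + length(x$mapped$missing),
              nrow(x$results), sum(x$results$passed_filters),
              sum(x$results$q_value < x$query$alpha, na.rm = TRUE),
              x$query$alpha))
  print(utils::head(ora_table(x)[, c("term_id", "term_name", "x", "y",
                                     "gene_count", "p_value", "q_value")],
                    10))
  invisible(x)
}
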