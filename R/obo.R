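#' Parse a Gene Ontology OBO file
#'
#' Reads the `[Term]` stanzas of an OBO 1.2/1.4 ontology file into a named
#' list of GO term records. Only `is_a` relations are retained as parent
#' links; `part_of`, `regulates` and other relationship lines are ignored
#' so the hierarchy used downstream is the conservative subsumption DAG.
#' Obsolete terms are flagged and their parent links dropped. Parent
#' references pointing outside the loaded ontology are removed so that
#' every retained parent resolves within the same load.
#'
#' @param path Path to an OBO file (plain text or gzip-compressed).
#' @return A list with components:
#'   \describe{
#'     \item{terms}{named list keyed by GO accession; each element has
#'       `term_id`, `name`, `namespace`, `parents` (character vector of
#'       `is_a` targets), `alt_ids` and `obsolete`.}
#'     \item{alt_to_primary}{named character vector mapping every
#'       `alt_id` to its primary accession.}
#'   }
#' @export
parse_go_obo <- function(path) {
  lines <- read_lines_any(path)
  # byte offset of the start of each line, for format diagnostics
  nb <- nchar(lines, type = "bytes") + 1L
  offsets <- c(0L, cumsum(nb))[seq_along(lines)]

  stanza_starts <- which(lines == "[Term]")
  boundaries <- which(grepl("^\\[", lines))
  terms <- vector("list", length(stanza_starts))
  ids <- character(length(stanza_starts))

  for (i in seq_along(stanza_starts)) {
    s <- stanza_starts[i]
    nxt <- boundaries[boundaries > s]
    e <- if (length(nxt)) nxt[1] - 1L else length(lines)
    body <- lines[(s + 1L):e]
    body <- body[nzchar(body)]

    get_vals <- function(tag) {
      hits <- body[startsWith(body, paste0(tag, ":"))]
      trimws(substring(hits, nchar(tag) + 2L))
    }
    id <- get_vals("id")
    if (length(id) == 0L || !nzchar(id[1])) {
      format_error("OBO [Term] stanza at byte offset %d has no id line",
                   offsets[s])
    }
    id <- id[1]
    obsolete <- any(tolower(get_vals("is_obsolete")) == "true")
    is_a <- get_vals("is_a")
    # "GO:0008152 ! metabolic process" -> target accession only
    parents <- unique(trimws(sub("!.*$", "", is_a)))
    if (obsolete) parents <- character(0)
    terms[[i]] <- list(
      term_id   = id,
      name      = if (length(n <- get_vals("name"))) n[1] else "",
      namespace = if (length(n <- get_vals("namespace"))) n[1] else "",
      parents   = parents,
      alt_ids   = unique(get_vals("alt_id")),
      obsolete  = obsolete
    )
    ids[i] <- id
  }
  names(terms) <- ids

  # drop parent references to terms absent from this load
  known <- names(terms)
  terms <- lapply(terms, function(t) {
    t$parents <- sort_c(intersect(t$parents, known))
    t
  })

  alt <- character(0)
  for (t in terms) {
    if (length(t$alt_ids)) {
      a <- t$alt_ids
      alt[a] <- t$term_id
    }
  }
  list(terms = terms, alt_to_primary = alt)
}

#' Extract the sub-ontology rooted at a term
#'
#' Returns the accessions of `root_id` plus every non-obsolete term from
#' which `root_id` is reachable by following `is_a` parent links (the
#' reflexive-transitive descendant closure). With the default root
#' GO:0008152 this is the metabolic-process sub-ontology that scopes the
#' knowledgebase.
#'
#' @param ontology A parsed ontology as returned by [parse_go_obo()], or
#'   its `terms` component.
#' @param root_id GO accession of the sub-ontology root.
#' @return Character vector of term accessions, sorted.
#' @export
metabolic_subontology <- function(ontology, root_id = "GO:0008152") {
  terms <- if (!is.null(ontology$terms)) ontology$terms else ontology
  if (!root_id %in% names(terms)) {
    lookup_error("root term %s not present in ontology", root_id)
  }
  # invert parent links once, then BFS from the root over children
  child_of <- new.env(parent = emptyenv())
  for (t in terms) {
    if (t$obsolete) next
    for (p in t$parents) {
      assign(p, c(get0(p, envir = child_of, ifnotfound = character(0)),
                  t$term_id), envir = child_of)
    }
  }
  seen <- new.env(parent = emptyenv())
  queue <- root_id
  assign(root_id, TRUE, envir = seen)
  while (length(queue)) {
    cur <- queue[[1]]
    queue <- queue[-1]
    for (ch in get0(cur, envir = child_of, ifnotfound = character(0))) {
      if (is.null(get0(ch, envir = seen))) {
        assign(ch, TRUE, envir = seen)
        queue <- c(queue, ch)
      }
    }
  }
  keep <- ls(seen)
  keep <- keep[!vapply(terms[keep], `[[`, logical(1), "obsolete")]
  sort_c(keep)
}

# All is_a ancestors of term_ids (not reflexive), restricted to `terms`.
go_ancestors <- function(terms, term_ids) {
  seen <- new.env(parent = emptyenv())
  queue <- unique(term_ids)
  anc <- character(0)
  while (length(queue)) {
    cur <- queue[[1]]
    queue <- queue[-1]
    t <- terms[[cur]]
    if (is.null(t)) next
    for (p in t$parents) {
      if (is.null(get0(p, envir = seen))) {
        assign(p, TRUE, envir = seen)
        anc <- c(anc, p)
        queue <- c(queue, p)
      }
    }
  }
  sort_c(setdiff(anc, term_ids))
}

# Resolve accessions through the alt_id map; unknown ids pass through.
resolve_alt_ids <- function(ids, alt_to_primary) {
  hit <- ids %in% names(alt_to_primary)
  ids[hit] <- unname(alt_to_primary[ids[hit]])
  ids
}
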