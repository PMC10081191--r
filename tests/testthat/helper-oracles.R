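# Independent oracles used across the suite. These deliberately avoid
# the code paths they check.

# Upper-tail hypergeometric probability by exhaustive enumeration of
# all C(y+a, b) equally likely draws; the first y population members
# are the successes.
hyper_tail_enum <- function(x, y, a, b) {
  n <- y + a
  if (b == 0) return(as.numeric(x <= 0))
  draws <- utils::combn(n, b)
  hits <- colSums(draws <= y)
  mean(hits >= x)
}

# Benjamini-Hochberg step-up by the direct formula
# q_(i) = min_{j >= i} m p_(j) / j, in input order.
bh_oracle <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Minimal SIF reader: returns list(edges = data.frame, isolated = chr).
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  is_edge <- lengths(parts) == 3L
  edges <- if (any(is_edge)) {
    m <- do.call(rbind, parts[is_edge])
    data.frame(source = m[, 1], relation = m[, 2], target = m[, 3],
               stringsAsFactors = FALSE)
  } else {
    data.frame(source = character(0), relation = character(0),
               target = character(0), stringsAsFactors = FALSE)
  }
  list(edges = edges, isolated = unlist(parts[lengths(parts) == 1L]))
}

# Brute-force set of terms from which `root` is reachable via parent
# links (recursive DFS), independent of the BFS in the package.
descendants_dfs <- function(terms, root) {
  reaches <- function(id, seen = character(0)) {
    if (id == root) return(TRUE)
    if (id %in% seen) return(FALSE)
    any(vapply(terms[[id]]$parents, reaches, logical(1),
               seen = c(seen, id))) %in% TRUE
  }
  ids <- names(terms)
  ids[vapply(ids, reaches, logical(1))]
}
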