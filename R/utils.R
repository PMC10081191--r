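# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Locale-independent character sort (C order), so serialized output is
# byte-identical across machines.
sort_c <- function(x) {
  if (is.null(x) || !length(x)) return(character(0))
  sort(x, method = "radix")
}

# Read a text file line-wise; gzfile() transparently handles both gzip
# and plain text, matching how the upstream sources ship (gzipped).
read_lines_any <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

stop_with <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "metago_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

format_error   <- function(msg, ...) stop_with("metago_format_error", msg, ...)
build_error    <- function(msg, ...) stop_with("metago_build_error", msg, ...)
analysis_error <- function(msg, ...) stop_with("metago_analysis_error", msg, ...)
lookup_error   <- function(msg, ...) stop_with("metago_lookup_error", msg, ...)

is_go_id       <- function(x) grepl("^GO:[0-9]{7}$", x)
is_compound_id <- function(x) grepl("^C[0-9]{5}$", x)
is_reaction_id <- function(x) grepl("^R[0-9]{5}$", x)
is_ec_number   <- function(x) grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", x)

# Strip a trailing accession version ("NM_000001.3" -> "NM_000001").
# Placeholders ("-") and unversioned accessions pass through unchanged.
strip_version <- function(x) {
  ifelse(grepl("\\.", x) & x != "-", sub("\\.[^.]*$", "", x), x)
}

# Run code with a private RNG stream, restoring the caller's stream after.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
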