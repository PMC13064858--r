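# Internal helpers shared across modules.

# Union-find with path halving; ids are 1..n.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <<- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# Connected components from an edge list over n nodes.
# Returns an integer membership vector (component ids are arbitrary but
# stable for a given input).
connected_components <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) {
      nxt <- parent[i]
      parent[i] <<- root
      i <- nxt
    }
    root
  }
  for (k in seq_along(from)) {
    ra <- find(from[k]); rb <- find(to[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

read_tsv_strict <- function(path, required_cols, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "")
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s table %s lacks required column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_bool <- function(x) {
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}
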