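# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# unordered pair key for edge / gene-pair identity
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# sorted-member key identifying a gene set irrespective of order
set_key <- function(members) {
  vapply(members, function(m) paste(sort(unique(m)), collapse = "\r"), character(1))
}

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)

# sample() that treats a length-1 x as a single value, not as 1:x
sample_from <- function(x, size, replace = FALSE, prob = NULL) {
  if (length(x) == 1) x[rep(1, size)] else sample(x, size, replace, prob)
}

assert_network <- function(network) {
  if (!igraph::is_igraph(network)) {
    stop_bad("expected an igraph network (see `read_edge_table()` / `simulate_ppi_network()`)")
  }
  if (is.null(igraph::V(network)$name)) {
    stop_bad("network vertices must carry gene symbols in the 'name' attribute")
  }
  if (is.null(igraph::E(network)$confidence) && igraph::ecount(network) > 0) {
    stop_bad("network edges must carry a 'confidence' attribute in (0, 1]")
  }
  invisible(network)
}

# confidence-weighted adjacency as a sparse symmetric matrix, gene order = V(network)
weighted_adjacency <- function(network) {
  assert_network(network)
  igraph::as_adjacency_matrix(network, attr = "confidence", sparse = TRUE)
}
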