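#' Read a STRING-style edge table and build the weighted network
#'
#' Expects a tab-separated file with three columns (gene A, gene B, combined
#' confidence). Scores either already lie in \[0,1\] or use the STRING
#' 0--1000 integer convention; the dialect is auto-detected (any score > 1
#' implies 0--1000 and is divided by 1000). Edges with normalized
#' confidence strictly above `threshold` are retained, symmetric duplicates
#' are collapsed keeping the maximum confidence, and self-loops are dropped
#' with a message.
#'
#' @param path Edge table file.
#' @param threshold Confidence cutoff in \[0,1\]; strict `>` comparison.
#' @param header Whether the first line is a header (auto-detected by
#'   default: a non-numeric third field on line 1).
#' @return igraph network with edge attribute `confidence`.
#' @export
read_edge_table <- function(path, threshold = 0.7, header = NULL) {
  if (!file.exists(path)) stop_bad("edge table not found: %s", path)
  if (threshold < 0 || threshold > 1) stop_bad("threshold must lie in [0,1]")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_bad("edge table %s is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (is.null(header)) {
    header <- length(fields[[1]]) >= 3 &&
      is.na(suppressWarnings(as.numeric(fields[[1]][3])))
  }
  start <- if (header) 2L else 1L
  if (start > length(fields)) stop_bad("edge table %s has no data rows", path)
  rows <- fields[seq(start, length(fields))]
  bad <- which(vapply(rows, length, integer(1)) < 3)
  if (length(bad)) {
    stop_bad("malformed edge row at line %d of %s (need 3 tab-separated fields)",
             bad[1] + start - 1L, path)
  }
  a <- vapply(rows, `[[`, character(1), 1)
  b <- vapply(rows, `[[`, character(1), 2)
  s <- suppressWarnings(as.numeric(vapply(rows, `[[`, character(1), 3)))
  if (anyNA(s)) {
    stop_bad("non-numeric score at line %d of %s",
             which(is.na(s))[1] + start - 1L, path)
  }
  if (any(s > 1)) s <- s / 1000   # STRING 0-1000 convention
  if (any(s < 0 | s > 1)) stop_bad("scores outside [0,1] after normalization")

  loops <- a == b
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    a <- a[!loops]; b <- b[!loops]; s <- s[!loops]
  }
  keep <- s > threshold
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  if (!length(a)) {
    stop_bad("no edges exceed confidence threshold %.3g; refusing to build an empty network",
             threshold)
  }
  # collapse symmetric duplicates keeping the maximum confidence
  key <- pair_key(a, b)
  ord <- order(key, -s)
  first <- !duplicated(key[ord])
  lo <- sub("\r.*$", "", key[ord][first])
  hi <- sub("^.*\r", "", key[ord][first])
  w <- s[ord][first]

  genes <- sort(unique(c(lo, hi)))
  network <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi), directed = FALSE,
    vertices = data.frame(name = genes)
  )
  igraph::E(network)$confidence <- w
  network
}

#' Write a network as a STRING-style edge table
#'
#' Three tab-separated columns: `gene_a`, `gene_b`, `combined_score` on the
#' 0--1000 integer scale. Confidences on a 1/1000 grid (as produced by the
#' synthetic generator) round-trip losslessly through [read_edge_table()].
#'
#' @param network igraph network with `confidence` edge attribute.
#' @param path Output file.
#' @export
write_edge_table <- function(network, path) {
  assert_network(network)
  el <- igraph::as_edgelist(network)
  df <- data.frame(gene_a = pmin(el[, 1], el[, 2]),
                   gene_b = pmax(el[, 1], el[, 2]),
                   combined_score = as.integer(round(igraph::E(network)$confidence * 1000)))
  df <- df[order(df$gene_a, df$gene_b), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT dialect
#'
#' Tab-separated lines `name<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate member symbols within a set are collapsed; duplicate set names
#' and empty sets are errors.
#'
#' @param path GMT file.
#' @return Named list of character vectors with a `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_bad("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3)
  if (length(short)) {
    stop_bad("GMT line %d has fewer than 3 fields (name, description, members...)",
             short[1])
  }
  nms <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nms)) {
    stop_bad("duplicate gene-set name: %s", nms[duplicated(nms)][1])
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  empty <- which(vapply(sets, length, integer(1)) == 0)
  if (length(empty)) stop_bad("gene set '%s' is empty", nms[empty[1]])
  names(sets) <- nms
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, character(1), 2), nms)
  sets
}

#' Write gene sets in GMT dialect
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @param descriptions Optional per-set descriptions (defaults to the set
#'   name, or the `descriptions` attribute if present).
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a gene annotation table
#'
#' Plain TSV with the `gene_table` columns (see [simulate_gene_table()]).
#' `read_gene_table()` validates symbol uniqueness, constraint and
#' druggability ranges, and the category/risk consistency rule (risk level
#' "high" exactly for evidence categories 1 and 2).
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("symbol", "category", "risk_level", "constraint",
              "gene_length_kb", "brain_expression", "pathway_count")
  missing <- setdiff(needed, names(df))
  if (length(missing)) stop_bad("gene table lacks column(s): %s",
                                paste(missing, collapse = ", "))
  if (anyDuplicated(df$symbol)) stop_bad("duplicate gene symbols in table")
  if (any(df$constraint < 0 | df$constraint > 1, na.rm = TRUE)) {
    stop_bad("constraint scores must lie in [0,1]")
  }
  if ("druggability" %in% names(df) &&
      any(df$druggability < 0 | df$druggability > 1, na.rm = TRUE)) {
    stop_bad("druggability must lie in [0,1] (or be missing)")
  }
  df$category <- as.character(df$category)
  hi <- df$category %in% c("1", "2")
  if (!all((df$risk_level == "high") == hi)) {
    stop_bad("risk_level must be 'high' exactly for evidence categories 1-2")
  }
  tibble::as_tibble(df)
}

#' @rdname read_gene_table
#' @param gene_table Tibble to write.
#' @export
write_gene_table <- function(gene_table, path) {
  utils::write.table(gene_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write an expression matrix (genes x samples TSV)
#'
#' @param path TSV file; first column holds gene symbols.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression
#' @param expression Matrix to write.
#' @export
write_expression <- function(expression, path) {
  df <- data.frame(symbol = rownames(expression), expression,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the giant component
#'
#' Returns the largest connected component (ties broken by the
#' lexicographically smallest member symbol) together with a component
#' report.
#'
#' @param network igraph network.
#' @return List: `network` (the giant component), `report` (tibble with one
#'   row per component: size and node fraction, largest first).
#' @export
giant_component <- function(network) {
  assert_network(network)
  if (igraph::vcount(network) == 0) stop_bad("network is empty")
  comp <- igraph::components(network)
  sizes <- comp$csize
  # representative (lexicographically smallest) symbol per component
  reps <- vapply(seq_along(sizes), function(i) {
    min(igraph::V(network)$name[comp$membership == i])
  }, character(1))
  ord <- order(-sizes, reps)
  report <- tibble::tibble(
    component = seq_along(sizes),
    size = sizes[ord],
    fraction = sizes[ord] / igraph::vcount(network),
    representative = reps[ord]
  )
  keep <- which(comp$membership == ord[1])
  sub <- igraph::induced_subgraph(network, keep)
  list(network = sub, report = report)
}
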