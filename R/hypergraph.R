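#' Maximal-clique hyperedges
#'
#' All maximal cliques of size at least `min_size` in the PPI network
#' (Bron--Kerbosch enumeration via igraph), each emitted once with sorted
#' members. A clique contained in a larger clique is not emitted: e.g. K4
#' yields one 4-gene hyperedge, not four triangles.
#'
#' @param network igraph network (simple, undirected).
#' @param min_size Minimum clique size (default 3).
#' @return List of sorted character vectors.
#' @export
clique_hyperedges <- function(network, min_size = 3) {
  assert_network(network)
  cl <- igraph::max_cliques(network, min = min_size)
  lapply(cl, function(v) sort(igraph::V(network)$name[as.integer(v)]))
}

#' Co-expression hyperedges
#'
#' Builds the gene graph whose edges are Pearson correlations strictly
#' above `r_threshold` and emits its connected components of size at least
#' `min_size` as hyperedges. Constant-expression genes are excluded with a
#' warning (their correlation is undefined).
#'
#' @param expression Genes x samples matrix (>= 3 samples).
#' @param r_threshold Correlation cutoff (default 0.7, strict `>`).
#' @param min_size Minimum component size (default 3).
#' @return List of sorted character vectors.
#' @export
coexpression_hyperedges <- function(expression, r_threshold = 0.7, min_size = 3) {
  if (ncol(expression) < 3) stop_bad("need >= 3 samples per gene")
  sds <- apply(expression, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant-expression gene(s) excluded", call. = FALSE)
    expression <- expression[sds > 0, , drop = FALSE]
  }
  if (nrow(expression) < min_size) return(list())
  r <- stats::cor(t(expression))
  adj <- r > r_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  keep <- which(comp$csize >= min_size)
  lapply(keep, function(k) sort(rownames(expression)[comp$membership == k]))
}

#' Pathway hyperedges from a gene-set collection
#'
#' Intersects each set with the network gene universe and keeps sets with
#' at least `min_size` surviving members.
#'
#' @param sets Named list of character vectors (e.g. [read_gene_sets()]).
#' @param universe Character vector of network genes.
#' @param min_size Minimum surviving size (default 3).
#' @return List of sorted character vectors (named after the sets).
#' @export
pathway_hyperedges <- function(sets, universe, min_size = 3) {
  out <- lapply(sets, function(s) sort(intersect(s, universe)))
  out[vapply(out, length, integer(1)) >= min_size]
}

#' Assemble the multi-evidence hypergraph
#'
#' Unions hyperedges from up to four provenance sources (`clique`,
#' `coexpression`, `autism_pathway`, `reactome_pathway`); hyperedges with
#' identical gene sets are merged (first provenance retained, weights
#' summed). Every hyperedge must have at least 3 members and reference
#' only known genes. Genes in no hyperedge are retained as isolated
#' (zero incidence row).
#'
#' @param sources Named list of hyperedge lists; names are provenance
#'   labels.
#' @param nodes Gene universe (character).
#' @param weights_by_provenance Named numeric hyperedge weights per
#'   provenance (default 1 each).
#' @param min_size Minimum hyperedge cardinality (default 3).
#' @return Object of class `gene_hypergraph`: `nodes`, `edges` (list of
#'   member vectors), `weight`, `provenance`, `H` (sparse incidence,
#'   nodes x hyperedges), `Dv` (weighted node degrees), `De` (hyperedge
#'   cardinalities).
#' @export
assemble_hypergraph <- function(sources, nodes, weights_by_provenance = NULL,
                                min_size = 3) {
  sources <- sources[vapply(sources, length, integer(1)) > 0]
  if (!length(sources)) stop_bad("no nonempty hyperedge source")
  prov_names <- names(sources)
  if (is.null(prov_names) || any(!nzchar(prov_names))) {
    stop_bad("sources must be a named list (provenance labels)")
  }
  w_default <- stats::setNames(rep(1, length(prov_names)), prov_names)
  if (!is.null(weights_by_provenance)) {
    w_default[names(weights_by_provenance)] <- weights_by_provenance
  }
  edges <- list(); weight <- numeric(); provenance <- character()
  seen <- character()
  for (prov in prov_names) {
    for (members in sources[[prov]]) {
      members <- sort(unique(members))
      if (length(members) < min_size) {
        stop_bad("hyperedge of size %d below the minimum cardinality %d",
                 length(members), min_size)
      }
      unknown <- setdiff(members, nodes)
      if (length(unknown)) {
        stop_bad("hyperedge references unknown gene(s): %s",
                 paste(utils::head(unknown, 3), collapse = ", "))
      }
      key <- paste(members, collapse = "\r")
      hit <- match(key, seen)
      if (is.na(hit)) {
        edges[[length(edges) + 1]] <- members
        weight <- c(weight, w_default[[prov]])
        provenance <- c(provenance, prov)
        seen <- c(seen, key)
      } else {
        weight[hit] <- weight[hit] + w_default[[prov]]
      }
    }
  }
  i <- unlist(lapply(seq_along(edges), function(e) match(edges[[e]], nodes)))
  j <- rep(seq_along(edges), vapply(edges, length, integer(1)))
  H <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(nodes), length(edges)),
                            dimnames = list(nodes, NULL))
  structure(
    list(nodes = nodes, edges = edges, weight = weight,
         provenance = provenance, H = H,
         Dv = as.numeric(H %*% weight),
         De = vapply(edges, length, integer(1))),
    class = "gene_hypergraph"
  )
}

#' @export
print.gene_hypergraph <- function(x, ...) {
  cat(sprintf("gene hypergraph: %d nodes, %d hyperedges (sizes %d-%d)\n",
              length(x$nodes), length(x$edges),
              min(x$De), max(x$De)))
  cat("  provenance:", paste(sprintf("%s=%d", names(table(x$provenance)),
                                     table(x$provenance)), collapse = ", "), "\n")
  invisible(x)
}

# normalized propagation operator Dv^-1/2 H W De^-1 H^T Dv^-1/2
# (shared by the Laplacian and the hypergraph convolution)
hypergraph_operator <- function(hg) {
  inv_sqrt <- ifelse(hg$Dv > 0, 1 / sqrt(hg$Dv), 0)
  Hs <- Matrix::Diagonal(x = inv_sqrt) %*% hg$H
  Theta <- Hs %*% Matrix::Diagonal(x = hg$weight / hg$De) %*% Matrix::t(Hs)
  Matrix::forceSymmetric((Theta + Matrix::t(Theta)) / 2)
}

#' Normalized hypergraph Laplacian
#'
#' `L = I - Dv^(-1/2) H W De^(-1) H^T Dv^(-1/2)`. Symmetric positive
#' semidefinite with smallest eigenvalue 0; isolated nodes contribute
#' identity rows.
#'
#' @param hg A `gene_hypergraph`.
#' @return Dense symmetric matrix (node order = `hg$nodes`).
#' @export
hypergraph_laplacian <- function(hg) {
  stopifnot(inherits(hg, "gene_hypergraph"))
  L <- Matrix::Diagonal(length(hg$nodes)) - hypergraph_operator(hg)
  m <- as.matrix(L)
  dimnames(m) <- list(hg$nodes, hg$nodes)
  m
}

#' Spectral communities of the hypergraph
#'
#' K-means (multiple restarts, fixed seed) on the k eigenvectors of the
#' normalized hypergraph Laplacian with smallest eigenvalues.
#'
#' @param hg A `gene_hypergraph`.
#' @param k Number of communities (2 <= k <= node count).
#' @param seed RNG seed.
#' @param nstart K-means restarts.
#' @return Tibble: `gene`, `community`.
#' @export
spectral_communities <- function(hg, k, seed = 1L, nstart = 25) {
  stopifnot(inherits(hg, "gene_hypergraph"))
  n <- length(hg$nodes)
  if (k < 2) stop_bad("k must be >= 2")
  if (k > n) stop_bad("k exceeds the node count")
  if (k == n) {
    return(tibble::tibble(gene = hg$nodes, community = seq_len(n)))
  }
  L <- hypergraph_laplacian(hg)
  eig <- eigen(L, symmetric = TRUE)
  U <- eig$vectors[, n - seq_len(k) + 1, drop = FALSE]  # smallest eigenvalues
  set.seed(seed)
  cl <- stats::kmeans(U, centers = k, nstart = nstart, iter.max = 100)
  tibble::tibble(gene = hg$nodes, community = cl$cluster)
}

#' Module cohesion scores
#'
#' Multiplicative composite per hyperedge: normalized mean perturbation
#' (mean member score divided by the global maximum score) x hub fraction
#' x internal PPI edge density (edges among members / C(size, 2)), clipped
#' to \[0, 1\]. Zero whenever any factor is zero.
#'
#' @param hg A `gene_hypergraph`.
#' @param scores Per-gene score tibble (`gene`, `score` or `final`).
#' @param hubs [classify_hubs()] result.
#' @param ppi_network igraph network supplying internal edge density.
#' @return Tibble: one row per hyperedge with the three factors and
#'   `cohesion`.
#' @export
module_cohesion <- function(hg, scores, hubs, ppi_network) {
  stopifnot(inherits(hg, "gene_hypergraph"))
  assert_network(ppi_network)
  val <- if ("score" %in% names(scores)) scores$score else scores$final
  names(val) <- scores$gene
  hub_set <- hubs$gene[hubs$is_hub]
  gmax <- max(val)
  el <- igraph::as_edgelist(ppi_network)
  edge_keys <- pair_key(el[, 1], el[, 2])
  purrr::map_dfr(seq_along(hg$edges), function(e) {
    members <- hg$edges[[e]]
    if (length(members) < 2) stop_bad("hyperedge %d has fewer than 2 members", e)
    if (anyNA(val[members])) stop_bad("missing scores for hyperedge members")
    pairs <- utils::combn(members, 2)
    density <- mean(pair_key(pairs[1, ], pairs[2, ]) %in% edge_keys)
    mean_pert <- mean(val[members])
    norm_pert <- if (gmax > 0) mean_pert / gmax else 0
    hub_frac <- mean(members %in% hub_set)
    tibble::tibble(
      hyperedge = e, size = length(members),
      provenance = hg$provenance[e],
      mean_perturbation = mean_pert,
      normalized_mean_perturbation = norm_pert,
      hub_fraction = hub_frac,
      internal_density = density,
      cohesion = max(0, min(1, norm_pert * hub_frac * density))
    )
  })
}

#' Hypergraph modularity via clique expansion
#'
#' Expands each hyperedge into its internal pairs with weight
#' `w_e / (|e| - 1)` per pair, sums weights over hyperedges, and evaluates
#' Newman--Girvan modularity of the given assignment on the expanded
#' weighted graph with resolution `gamma`.
#'
#' @param hg A `gene_hypergraph`.
#' @param assignment Tibble (`gene`, `community`) or named vector.
#' @param gamma Resolution parameter (default 1).
#' @return Modularity value (numeric scalar).
#' @export
hypergraph_modularity <- function(hg, assignment, gamma = 1.0) {
  stopifnot(inherits(hg, "gene_hypergraph"))
  if (is.data.frame(assignment)) {
    assignment <- stats::setNames(assignment$community, assignment$gene)
  }
  if (!length(assignment)) stop_bad("empty assignment")
  acc <- list()
  for (e in seq_along(hg$edges)) {
    members <- hg$edges[[e]]
    pw <- hg$weight[e] / (length(members) - 1)
    pairs <- utils::combn(members, 2)
    acc[[e]] <- data.frame(a = pairs[1, ], b = pairs[2, ], w = pw)
  }
  df <- do.call(rbind, acc)
  df <- stats::aggregate(w ~ a + b, data = df, FUN = sum)
  g <- igraph::graph_from_data_frame(df[, c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = hg$nodes))
  membership <- as.integer(factor(assignment[hg$nodes]))
  if (anyNA(membership)) stop_bad("assignment must cover every hypergraph node")
  igraph::modularity(g, membership, weights = df$w, resolution = gamma)
}

#' Hypergraph summary with the multi-way relationship statistic
#'
#' Counts the gene pairs covered by hyperedges: the total pair slots
#' `sum(choose(|e|, 2))`, the unique covered pairs, the number of those
#' already present as pairwise PPI edges, and the multi-way statistic
#' (covered pairs not present as PPI edges), together with its percentage
#' of the pairwise edge count.
#'
#' @param hg A `gene_hypergraph`.
#' @param network The pairwise PPI igraph network.
#' @return One-row tibble.
#' @export
hypergraph_summary <- function(hg, network) {
  stopifnot(inherits(hg, "gene_hypergraph"))
  assert_network(network)
  el <- igraph::as_edgelist(network)
  edge_keys <- unique(pair_key(el[, 1], el[, 2]))
  covered <- unique(unlist(lapply(hg$edges, function(m) {
    p <- utils::combn(m, 2); pair_key(p[1, ], p[2, ])
  })))
  slots <- sum(choose(hg$De, 2))
  already <- sum(covered %in% edge_keys)
  multiway <- length(covered) - already
  tibble::tibble(
    n_hyperedges = length(hg$edges),
    mean_size = mean(hg$De), median_size = stats::median(hg$De),
    pair_slots = slots,
    covered_pairs = length(covered),
    pairwise_edges = length(edge_keys),
    pairs_already_present = already,
    multiway_relationships = multiway,
    multiway_gain_pct = 100 * multiway / length(edge_keys)
  )
}
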