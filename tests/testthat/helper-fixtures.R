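# shared fixtures and independent brute-force oracles

toy_network <- function(edges, confidence = NULL, vertices = NULL) {
  df <- data.frame(from = edges[[1]], to = edges[[2]])
  g <- igraph::graph_from_data_frame(df, directed = FALSE, vertices = vertices)
  igraph::E(g)$confidence <- confidence %||% rep(1, nrow(df))
  g
}

path_graph <- function() toy_network(list(c("A", "B"), c("B", "C")))
triangle_graph <- function() toy_network(list(c("A", "B", "A"), c("B", "C", "C")))
star_graph <- function(n_leaves = 4) {
  toy_network(list(rep("HUB", n_leaves), paste0("L", seq_len(n_leaves))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_toy_graph <- function(n, p = 0.4) {
  A <- matrix(stats::runif(n * n) < p, n, n)
  A[lower.tri(A, diag = TRUE)] <- FALSE
  A <- A | t(A)
  idx <- which(A & upper.tri(A), arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  nm <- sprintf("v%02d", seq_len(n))
  toy_network(list(nm[idx[, 1]], nm[idx[, 2]]),
              vertices = data.frame(name = nm))
}

# --- brute-force maximal cliques via neighbor bitmasks -----------------
brute_maximal_cliques <- function(network, min_size = 3) {
  n <- igraph::vcount(network)
  stopifnot(n <= 16)
  nm <- igraph::V(network)$name
  A <- as.matrix(igraph::as_adjacency_matrix(network))
  nbr <- vapply(seq_len(n), function(i) sum(2^(which(A[i, ] > 0) - 1)), numeric(1))
  out <- list()
  for (S in seq_len(2^n - 1)) {
    members <- which(bitwAnd(S, 2^(seq_len(n) - 1)) > 0)
    if (length(members) < min_size) next
    is_clique <- all(vapply(members, function(i) {
      need <- S - 2^(i - 1)
      bitwAnd(nbr[i], need) == need
    }, logical(1)))
    if (!is_clique) next
    maximal <- !any(vapply(setdiff(seq_len(n), members), function(v) {
      bitwAnd(nbr[v], S) == S
    }, logical(1)))
    if (maximal) out[[length(out) + 1]] <- sort(nm[members])
  }
  out
}

# --- all-pairs shortest paths + betweenness/closeness oracle -----------
brute_path_stats <- function(network) {
  n <- igraph::vcount(network)
  nm <- igraph::V(network)$name
  A <- as.matrix(igraph::as_adjacency_matrix(network)) > 0
  D <- matrix(Inf, n, n); diag(D) <- 0
  D[A] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  # shortest-path counts by recursion on distance
  nsp <- matrix(0, n, n); diag(nsp) <- 1
  for (len in seq_len(n)) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (is.finite(D[s, t]) && D[s, t] == len) {
        preds <- which(A[, t] & D[s, ] == len - 1)
        nsp[s, t] <- sum(nsp[s, preds])
      }
    }
  }
  btw <- vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(D[s, t]) || nsp[s, t] == 0) next
      if (D[s, v] + D[v, t] == D[s, t]) {
        tot <- tot + nsp[s, v] * nsp[v, t] / nsp[s, t]
      }
    }
    tot
  }, numeric(1))
  clo <- vapply(seq_len(n), function(i) {
    di <- D[i, ]; di <- di[is.finite(di) & di > 0]
    if (!length(di)) 0 else length(di) / sum(di)
  }, numeric(1))
  list(betweenness = stats::setNames(btw, nm),
       closeness = stats::setNames(clo, nm))
}

# --- exact hypergeometric upper tail by enumeration --------------------
brute_hyper_upper <- function(obs, set_size, universe, test_size) {
  ks <- max(0, set_size + test_size - universe):min(set_size, test_size)
  probs <- vapply(ks, function(k) {
    choose(set_size, k) * choose(universe - set_size, test_size - k) /
      choose(universe, test_size)
  }, numeric(1))
  sum(probs[ks >= obs])
}

# --- Fisher two-sided p by full enumeration ----------------------------
brute_fisher_p <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; k <- a + b
  support <- max(0, k - nn):min(k, m)
  mass <- vapply(support, function(x) {
    choose(m, x) * choose(nn, k - x) / choose(m + nn, k)
  }, numeric(1))
  obs <- mass[match(a, support)]
  sum(mass[mass <= obs * (1 + 1e-7)])
}

# --- independently coded Steiger Z (different algebraic route) ---------
oracle_steiger_z <- function(r12, r13, r23, n) {
  rbar <- (r12 + r13) / 2
  psi <- r23 * (1 - rbar^2 - rbar^2) -
    (rbar^2 / 2) * ((1 - rbar^2 - rbar^2) - r23^2)
  cov_z <- psi / (1 - rbar^2)^2
  (atanh(r12) - atanh(r13)) * sqrt((n - 3) / (2 - 2 * cov_z))
}

# --- textbook clustering indices (independent implementations) ---------
oracle_cluster_indices <- function(X, cl) {
  cl <- as.integer(factor(cl))
  n <- nrow(X); k <- max(cl)
  d <- as.matrix(stats::dist(X))
  sil <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(cl == cl[i]), i)
    if (!length(same)) { sil[i] <- 0; next }
    a <- mean(d[i, same])
    b <- min(vapply(setdiff(seq_len(k), cl[i]),
                    function(c2) mean(d[i, cl == c2]), numeric(1)))
    sil[i] <- (b - a) / max(a, b)
  }
  g <- colMeans(X)
  centers <- do.call(rbind, lapply(seq_len(k), function(c2) {
    colMeans(X[cl == c2, , drop = FALSE])
  }))
  B <- sum(vapply(seq_len(k), function(c2) {
    sum(cl == c2) * sum((centers[c2, ] - g)^2)
  }, numeric(1)))
  W <- sum(vapply(seq_len(n), function(i) sum((X[i, ] - centers[cl[i], ])^2),
                  numeric(1)))
  ch <- (B / (k - 1)) / (W / (n - k))
  S <- vapply(seq_len(k), function(c2) {
    mean(sqrt(rowSums(sweep(X[cl == c2, , drop = FALSE], 2,
                            centers[c2, ])^2)))
  }, numeric(1))
  db <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (S[i] + S[j]) / sqrt(sum((centers[i, ] - centers[j, ])^2))
    }, numeric(1)))
  }, numeric(1)))
  list(silhouette = mean(sil), ch = ch, db = db)
}

# medium synthetic benchmark shared across test files (built once)
shared_bench <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_benchmark(synthetic_config(n_genes = 300, seed = 42),
                                   n_samples = 40)
    }
    cache
  }
})
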