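#' Per-gene centrality profile
#'
#' Computes six node-level topology measures on the unweighted structure of
#' the network: degree, degree centrality (degree / (n-1)), raw betweenness
#' (shortest-path pair counts), component-wise closeness (inverse mean
#' shortest-path distance within the node's connected component),
#' eigenvector centrality, and the local clustering coefficient (triangle
#' density of the neighborhood; 0 for nodes of degree < 2).
#'
#' Betweenness is reported raw, not normalized, matching the magnitude
#' convention of hub/non-hub comparisons on networks of this size.
#'
#' @param network igraph network.
#' @return Tibble, one row per gene.
#' @export
centrality_profile <- function(network) {
  assert_network(network)
  n <- igraph::vcount(network)
  if (n < 2) stop_bad("centralities are undefined on a single-node network")
  genes <- igraph::V(network)$name
  deg <- igraph::degree(network)
  btw <- igraph::betweenness(network, directed = FALSE, weights = NA)
  # component-wise closeness: (|C|-1) / sum of distances within component
  d <- igraph::distances(network, weights = NA)
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, ]
    di <- di[is.finite(di) & di > 0]
    if (!length(di)) 0 else length(di) / sum(di)
  }, numeric(1))
  eig <- igraph::eigen_centrality(network, weights = NA)$vector
  cc <- igraph::transitivity(network, type = "local", isolates = "zero")
  tibble::tibble(
    gene = genes,
    degree = as.integer(unname(deg)),
    degree_centrality = unname(deg) / (n - 1),
    betweenness = unname(btw),
    closeness = unname(clo),
    eigenvector = unname(eig),
    clustering_coef = unname(cc)
  )
}

#' Static composite perturbation score
#'
#' The hub-classification statistic: the product of a gene's degree
#' centrality and the mean confidence of its incident edges. Isolated nodes
#' score 0. Multiplying all confidences by a constant c scales all scores
#' by c. With `max_normalize = TRUE` the scores are additionally divided by
#' their maximum (an alternative normalization; the plain product is the
#' default because published hub-level summary statistics are consistent
#' with it and not with max-normalization).
#'
#' @param network igraph network with edge `confidence`.
#' @param max_normalize Divide by the maximum score (default `FALSE`).
#' @return Tibble with `gene` and `score`.
#' @export
perturbation_scores <- function(network, max_normalize = FALSE) {
  assert_network(network)
  n <- igraph::vcount(network)
  genes <- igraph::V(network)$name
  if (n < 2) stop_bad("scores are undefined on a single-node network")
  W <- weighted_adjacency(network)
  deg <- igraph::degree(network)
  wsum <- Matrix::rowSums(W)
  mean_conf <- ifelse(deg > 0, wsum / deg, 0)
  score <- (deg / (n - 1)) * mean_conf
  if (max_normalize) {
    mx <- max(score)
    if (mx > 0) score <- score / mx
  }
  tibble::tibble(gene = genes, score = as.numeric(score))
}

#' Classify hub genes by percentile threshold
#'
#' The threshold is the linear-interpolation percentile of the score
#' distribution (the `stats::quantile()` type-7 convention, index
#' 0.01*percentile*(n-1) over the order statistics); genes strictly above
#' the threshold are hubs. For any set of distinct scores this yields a hub
#' fraction of approximately (100-percentile)%, e.g. exactly 179 of 893.
#' If all scores are identical, no gene is a hub and a warning is raised.
#'
#' @param scores Tibble from [perturbation_scores()] (columns `gene`,
#'   `score`) or a named numeric vector.
#' @param percentile Percentile cutoff (default 80).
#' @return Tibble of class `hub_classification` with columns `gene`,
#'   `score`, `is_hub`; the realized cutoff is stored in the
#'   `threshold_value` attribute.
#' @export
classify_hubs <- function(scores, percentile = 80) {
  if (is.numeric(scores)) {
    scores <- tibble::tibble(
      gene = names(scores) %||% as.character(seq_along(scores)),
      score = as.numeric(scores)
    )
  }
  if (nrow(scores) < 5) stop_bad("need at least 5 scores to classify hubs")
  thr <- unname(stats::quantile(scores$score, percentile / 100, type = 7))
  if (max(scores$score) == min(scores$score)) {
    warning("all scores identical; no gene classified as hub", call. = FALSE)
  }
  out <- dplyr::mutate(scores, is_hub = .data$score > thr)
  attr(out, "threshold_value") <- thr
  attr(out, "percentile") <- percentile
  class(out) <- c("hub_classification", class(out))
  out
}

#' Maximum-likelihood power-law fit of a degree sequence
#'
#' Continuous MLE exponent `alpha = 1 + n / sum(log(x/xmin))` for the tail
#' `x >= xmin`. By default the cutoff is the minimum positive degree (the
#' whole distribution is fitted, the convention the synthetic generator is
#' calibrated against); `xmin = "scan"` instead selects the cutoff by
#' minimizing the Kolmogorov--Smirnov distance between the empirical tail
#' and the fitted law, and a numeric `xmin` fixes it. The log--log
#' goodness of fit (`r_squared`) comes from least squares on the binned
#' empirical degree distribution, and `gof_p` from a chi-squared test of
#' the binned tail against the fitted law.
#'
#' @param degrees Positive degree sequence (zeros are dropped).
#' @param xmin `NULL` (minimum positive degree), `"scan"` (KS selection,
#'   requires >= 50 positive degrees), or a fixed numeric cutoff.
#' @return Object of class `power_law_fit` with fields `alpha`, `xmin`,
#'   `r_squared`, `gof_p`, `n_tail`.
#' @export
fit_power_law <- function(degrees, xmin = NULL) {
  x <- degrees[degrees > 0]
  if (!length(x)) stop_bad("no positive degrees")
  if (max(x) == min(x)) stop_bad("degenerate constant degree sequence")
  scan <- identical(xmin, "scan")
  if (scan && length(x) < 50) {
    stop_bad("need >= 50 positive degrees for automatic cutoff selection")
  }
  mle <- function(tail, xm) 1 + length(tail) / sum(log(tail / xm))
  if (is.null(xmin)) xmin <- min(x)
  if (scan) {
    cands <- sort(unique(x))
    cands <- cands[cands <= stats::quantile(x, 0.9)]
    best <- NULL
    for (xm in cands) {
      tail <- sort(x[x >= xm])
      if (length(tail) < 25) next
      a <- mle(tail, xm)
      cdf_emp <- seq_along(tail) / length(tail)
      cdf_fit <- 1 - (tail / xm)^(1 - a)
      D <- max(abs(cdf_emp - cdf_fit))
      if (is.null(best) || D < best$D) best <- list(alpha = a, xmin = xm, D = D)
    }
    if (is.null(best)) stop_bad("no viable cutoff with >= 25 tail points")
    xmin <- best$xmin
  }
  tail <- x[x >= xmin]
  alpha <- mle(tail, xmin)

  # log-log least squares on the empirical degree distribution of the tail
  tb <- table(tail)
  k <- as.numeric(names(tb))
  pk <- as.numeric(tb) / length(tail)
  r_squared <- if (length(k) >= 3) {
    fit <- stats::lm(log(pk) ~ log(k))
    suppressWarnings(summary(fit)$r.squared)
  } else NA_real_

  # chi-squared GOF against the fitted continuous law on [xmin, max]
  gof_p <- tryCatch({
    nb <- max(3, min(10, floor(length(tail) / 10)))
    brks <- unique(stats::quantile(tail, probs = seq(0, 1, length.out = nb + 1)))
    brks[1] <- xmin; brks[length(brks)] <- max(tail) + 1e-9
    obs <- as.numeric(table(cut(tail, brks, include.lowest = TRUE)))
    cdf <- function(q) {
      (1 - (q / xmin)^(1 - alpha)) / (1 - (max(tail) / xmin)^(1 - alpha))
    }
    p <- diff(vapply(brks, cdf, numeric(1)))
    p <- pmax(p, 1e-12); p <- p / sum(p)
    stat <- sum((obs - length(tail) * p)^2 / (length(tail) * p))
    df <- max(1, length(obs) - 2)
    stats::pchisq(stat, df, lower.tail = FALSE)
  }, error = function(e) NA_real_)

  structure(
    list(alpha = alpha, xmin = xmin, r_squared = r_squared,
         gof_p = gof_p, n_tail = length(tail)),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law fit: alpha = %.3f (xmin = %g, tail n = %d)\n",
              x$alpha, x$xmin, x$n_tail))
  cat(sprintf("  log-log R^2 = %.3f, chi^2 GOF p = %.3g\n",
              x$r_squared, x$gof_p))
  invisible(x)
}

#' Small-world statistics against Erdos--Renyi baselines
#'
#' Mean local clustering C, characteristic path length L (over reachable
#' pairs), the same quantities averaged over `n_random` random G(n, m)
#' graphs with matched node and edge counts, the clustering enrichment
#' ratio, and the degree assortativity (Pearson correlation of degrees
#' over edges; `NaN` with a warning when degenerate).
#'
#' @param network igraph network (applied to the giant component for L).
#' @param n_random Number of random baseline draws.
#' @param seed RNG seed for the baseline draws.
#' @return Tibble with one row: `C`, `L`, `C_random`, `L_random`,
#'   `C_ratio`, `assortativity`.
#' @export
small_world_stats <- function(network, n_random = 20, seed = 1L) {
  assert_network(network)
  if (n_random < 1) stop_bad("n_random must be >= 1")
  n <- igraph::vcount(network)
  m <- igraph::ecount(network)
  C <- igraph::transitivity(network, type = "localaverage", isolates = "zero")
  L <- igraph::mean_distance(network, directed = FALSE, unconnected = TRUE)
  set.seed(seed)
  rand <- purrr::map(seq_len(n_random), function(i) {
    g <- igraph::sample_gnm(n, m)
    c(C = igraph::transitivity(g, type = "localaverage", isolates = "zero"),
      L = igraph::mean_distance(g, directed = FALSE, unconnected = TRUE))
  })
  C_random <- mean(purrr::map_dbl(rand, "C"))
  L_random <- mean(purrr::map_dbl(rand, "L"))
  assort <- suppressWarnings(igraph::assortativity_degree(network, directed = FALSE))
  if (!is.finite(assort)) {
    warning("assortativity undefined (zero degree variance over edges); reporting NaN",
            call. = FALSE)
    assort <- NaN
  }
  tibble::tibble(C = C, L = L, C_random = C_random, L_random = L_random,
                 C_ratio = ifelse(C_random > 0, C / C_random, NaN),
                 assortativity = assort)
}

#' Hub-classification robustness under random edge removal
#'
#' For each removal fraction, repeatedly deletes that fraction of edges
#' uniformly at random, re-runs [perturbation_scores()] +
#' [classify_hubs()], and measures the percentage of original hub genes
#' (restricted to genes remaining in the largest connected component of
#' the perturbed network) that keep hub status. Fraction 0 is allowed as a
#' control and gives exactly 100%.
#'
#' @param network igraph network.
#' @param fractions Removal fractions in \[0, 1).
#' @param n_iter Iterations per fraction.
#' @param seed RNG seed.
#' @param percentile Hub percentile (default 80).
#' @return Tibble: `fraction`, `mean_consistency` (percent),
#'   `sd_consistency`, `n_iterations`.
#' @export
edge_removal_robustness <- function(network, fractions = c(0.1, 0.2, 0.3),
                                    n_iter = 100, seed = 1L, percentile = 80) {
  assert_network(network)
  if (any(fractions < 0 | fractions >= 1)) stop_bad("fractions must lie in [0, 1)")
  hubs0 <- classify_hubs(perturbation_scores(network), percentile)
  orig_hubs <- hubs0$gene[hubs0$is_hub]
  m <- igraph::ecount(network)
  set.seed(seed)
  purrr::map_dfr(fractions, function(f) {
    cons <- vapply(seq_len(n_iter), function(i) {
      drop <- sample(m, round(f * m))
      g <- if (length(drop)) igraph::delete_edges(network, drop) else network
      comp <- igraph::components(g)
      giant <- igraph::V(g)$name[comp$membership == which.max(comp$csize)]
      hubs <- classify_hubs(perturbation_scores(g), percentile)
      surviving <- intersect(orig_hubs, giant)
      if (!length(surviving)) return(NA_real_)
      still <- hubs$gene[hubs$is_hub]
      100 * mean(surviving %in% still)
    }, numeric(1))
    tibble::tibble(fraction = f,
                   mean_consistency = mean(cons, na.rm = TRUE),
                   sd_consistency = stats::sd(cons),
                   n_iterations = n_iter)
  })
}

#' Hub-classification stability under k-fold edge sampling
#'
#' Each fold retains `sample_frac` of the edges uniformly at random;
#' consistency is the percentage of genes whose hub / non-hub status in
#' the fold matches the full-network classification.
#'
#' @param network igraph network.
#' @param k Number of folds (>= 2).
#' @param sample_frac Edge retention fraction in (0, 1].
#' @param seed RNG seed.
#' @param percentile Hub percentile.
#' @return Tibble with one row per fold (`fold`, `hub_count`,
#'   `consistency`) plus attributes `mean_consistency`, `sd_consistency`.
#' @export
edge_cv_stability <- function(network, k = 5, sample_frac = 0.8, seed = 1L,
                              percentile = 80) {
  assert_network(network)
  if (k < 2) stop_bad("k must be >= 2")
  if (sample_frac <= 0 || sample_frac > 1) stop_bad("sample_frac must lie in (0, 1]")
  full <- classify_hubs(perturbation_scores(network), percentile)
  m <- igraph::ecount(network)
  set.seed(seed)
  res <- purrr::map_dfr(seq_len(k), function(fold) {
    keep <- sample(m, round(sample_frac * m))
    g <- igraph::subgraph_from_edges(network, keep, delete.vertices = FALSE)
    # subgraph_from_edges keeps all vertices; recompute on retained edges
    hubs <- classify_hubs(perturbation_scores(g), percentile)
    agree <- hubs$is_hub[match(full$gene, hubs$gene)] == full$is_hub
    tibble::tibble(fold = fold,
                   hub_count = sum(hubs$is_hub),
                   consistency = 100 * mean(agree))
  })
  attr(res, "mean_consistency") <- mean(res$consistency)
  attr(res, "sd_consistency") <- stats::sd(res$consistency)
  res
}
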