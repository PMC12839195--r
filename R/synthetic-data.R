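#' Simulate a scale-free confidence-weighted PPI network
#'
#' Generates an undirected simple graph whose degree sequence follows a
#' power law calibrated so that the continuous maximum-likelihood exponent
#' recovered by [fit_power_law()] matches `target_exponent` as the network
#' grows, and whose edges carry confidences drawn uniformly from
#' `conf_range`. Target degrees are drawn from a truncated power law (the
#' structural cutoff is `sqrt(n * mean_degree)`) and edges are realized with
#' a fitness (Chung-Lu) rule; because the truncation biases the plain MLE
#' upward, the sampling exponent is solved internally so that the generator
#' honours its contract on the *fitted* exponent. Identical seeds give
#' identical graphs.
#'
#' @param config A [synthetic_config()].
#' @return A list with components `network` (igraph, edge attribute
#'   `confidence`) and `truth` (planted ground truth: `hub_ids`, per-gene
#'   `target_degree`, later enriched by the other generators).
#' @export
simulate_ppi_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_genes
  if (n < 20) stop_bad("n_genes must be >= 20 for a meaningful network")
  set.seed(config$seed)
  genes <- sprintf("G%04d", seq_len(n))

  theta <- sample_target_degrees(n, config$target_exponent, config$mean_degree)

  # fitness / Chung-Lu realization: P(i~j) = min(1, theta_i theta_j / sum)
  S <- sum(theta)
  P <- outer(theta, theta) / S
  P[P > 1] <- 1
  U <- matrix(stats::runif(n * n), n, n)
  up <- (U < P) & upper.tri(P)
  idx <- which(up, arr.ind = TRUE)

  # confidences on a 1/1000 grid strictly inside conf_range so the
  # STRING-style integer writer round-trips losslessly
  lo <- floor(config$conf_range[1] * 1000) + 1
  hi <- round(config$conf_range[2] * 1000)
  conf <- sample_from(seq(lo, hi), nrow(idx), replace = TRUE) / 1000

  network <- igraph::graph_from_data_frame(
    data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]]),
    directed = FALSE,
    vertices = data.frame(name = genes)
  )
  igraph::E(network)$confidence <- conf

  hub_ids <- genes[theta >= stats::quantile(theta, 1 - config$frac_hub)]
  truth <- list(
    hub_ids = hub_ids,
    target_degree = stats::setNames(theta, genes),
    module_assignments = NULL,
    pathway_membership = NULL
  )
  list(network = network, truth = truth)
}

# Draw n target degrees from a truncated power law whose *fitted*
# (untruncated continuous MLE) exponent equals `target`; pure given the
# RNG state on entry. The lower truncation point is anchored at 1.5
# expected edges per node so that very few nodes end up isolated and the
# realized network keeps a dominant giant component; the upper cutoff is
# then solved for the requested mean degree (capped at the structural
# cutoff sqrt(n * mean_degree)). When the anchored solve is infeasible
# (very small networks) the roles flip: the cutoff is pinned and the
# lower truncation point solved instead.
sample_target_degrees <- function(n, target, mean_degree) {
  cutoff <- sqrt(n * mean_degree)
  floor_k <- min(1.5, mean_degree / 2)
  u <- stats::runif(n)
  pu <- stats::runif(n)

  pl_mean <- function(a, kmin, kmax) {
    mom <- function(p) {
      q <- p - a + 1
      if (abs(q) < 1e-9) log(kmax / kmin) else (kmax^q - kmin^q) / q
    }
    mom(1) / mom(0)
  }
  draw <- function(a, kmin, kmax) {
    q <- 1 - a
    th <- ((kmax^q - kmin^q) * u + kmin^q)^(1 / q)
    th * mean_degree / mean(th)
  }
  theta_of <- function(a) {
    f_hi <- function(k) pl_mean(a, floor_k, k) - mean_degree
    if (f_hi(cutoff) >= 0) {
      kmax <- stats::uniroot(f_hi, c(floor_k * 1.01, cutoff), tol = 1e-8)$root
      return(draw(a, floor_k, kmax))
    }
    f_lo <- function(k) pl_mean(a, k, cutoff) - mean_degree
    if (f_lo(1e-4) > 0) return(NULL)
    kmin <- stats::uniroot(f_lo, c(1e-4, mean_degree * 2), tol = 1e-8)$root
    draw(a, kmin, cutoff)
  }
  mle <- function(x) {
    x <- x[x > 0]
    1 + length(x) / sum(log(x / min(x)))
  }
  objective <- function(a) {
    th <- theta_of(a)
    if (is.null(th)) return(NA_real_)
    mle(stats::qpois(pu, th)) - target
  }
  grid <- seq(1.01, 2.9, by = 0.1)
  vals <- vapply(grid, objective, numeric(1))
  ok <- which(!is.na(vals))
  if (!length(ok)) stop_bad("degree sampler infeasible for this configuration")
  flips <- ok[which(diff(sign(vals[ok])) != 0)]
  a <- if (length(flips)) {
    i <- flips[1]
    stats::uniroot(objective, grid[c(i, i + 1)], tol = 1e-4)$root
  } else {
    grid[ok[which.min(abs(vals[ok]))]]
  }
  theta_of(a)
}

#' Simulate per-gene annotations
#'
#' One row per network gene: evidence category, derived risk level,
#' constraint (pLI-like, in \[0,1\]), gene length, mean brain expression
#' (log scale), pathway participation count and druggability. Planted hub
#' genes receive an additive `hub_effect_sd`-SD shift on constraint, brain
#' expression and pathway participation so that clustering on
#' hub-independent features carries real signal.
#'
#' @param network igraph network from [simulate_ppi_network()].
#' @param truth Planted truth from [simulate_ppi_network()].
#' @param config The same [synthetic_config()].
#' @return A tibble (class `gene_table` contract: columns `symbol`,
#'   `category`, `risk_level`, `constraint`, `gene_length_kb`,
#'   `brain_expression`, `pathway_count`, `druggability`).
#' @export
simulate_gene_table <- function(network, truth, config) {
  assert_network(network)
  genes <- igraph::V(network)$name
  n <- length(genes)
  if (n == 0) stop_bad("network is empty")
  set.seed(config$seed + 1L)

  probs <- config$frac_category
  category <- sample(names(probs), n, replace = TRUE, prob = probs)
  is_hub <- genes %in% truth$hub_ids

  base_sd_constraint <- 0.2
  constraint <- stats::rbeta(n, 2, 2.5) +
    is_hub * config$hub_effect_sd * base_sd_constraint
  constraint <- pmin(pmax(constraint, 0), 1)

  base_sd_expr <- 1
  brain_expression <- stats::rnorm(n, mean = 2.5, sd = base_sd_expr) +
    is_hub * config$hub_effect_sd * base_sd_expr

  gene_length_kb <- stats::rlnorm(n, meanlog = log(30), sdlog = 1)
  pathway_count <- stats::rpois(n, lambda = 3 + 6 * is_hub)

  druggability <- stats::runif(n)
  missing <- stats::runif(n) < config$drug_missing_frac
  druggability[missing] <- NA_real_

  tibble::tibble(
    symbol = genes,
    category = category,
    risk_level = category_to_risk(category),
    constraint = constraint,
    gene_length_kb = gene_length_kb,
    brain_expression = brain_expression,
    pathway_count = pathway_count,
    druggability = druggability
  )
}

#' Plant co-expression modules
#'
#' Assigns disjoint module memberships of sizes drawn from
#' `module_size_range` to randomly chosen genes and records them in the
#' planted truth; genes outside any module get `NA`.
#'
#' @inheritParams simulate_gene_table
#' @return Updated `truth` list with `module_assignments` (named integer
#'   vector, `NA` for unassigned genes).
#' @export
plant_modules <- function(network, truth, config) {
  assert_network(network)
  genes <- igraph::V(network)$name
  set.seed(config$seed + 2L)
  sizes <- sample_from(seq(config$module_size_range[1], config$module_size_range[2]),
                       config$n_modules, replace = TRUE)
  if (sum(sizes) > length(genes)) stop_bad("modules do not fit into the gene universe")
  pool <- sample(genes, sum(sizes))
  assignment <- stats::setNames(rep(NA_integer_, length(genes)), genes)
  offset <- 0
  for (m in seq_along(sizes)) {
    assignment[pool[offset + seq_len(sizes[m])]] <- m
    offset <- offset + sizes[m]
  }
  truth$module_assignments <- assignment
  truth
}

#' Simulate a gene-by-sample expression matrix
#'
#' Genes sharing a planted module are generated from one shared latent
#' factor plus independent Gaussian noise (`noise_sd`), so the population
#' within-module Pearson correlation is `1/(1 + noise_sd^2)`; off-module
#' genes are independent noise with expected correlation 0. `noise_sd = 0`
#' gives exact within-module correlation 1.
#'
#' @param truth Planted truth carrying `module_assignments`
#'   (see [plant_modules()]).
#' @param n_samples Number of samples (columns); at least 3.
#' @param config The [synthetic_config()].
#' @return Numeric matrix, genes in rows (rownames = symbols).
#' @export
simulate_expression <- function(truth, n_samples, config) {
  if (is.null(truth$module_assignments)) {
    stop_bad("truth has no module assignments; call plant_modules() first")
  }
  if (n_samples < 3) stop_bad("n_samples < 3: correlation would be degenerate")
  set.seed(config$seed + 3L)
  assignment <- truth$module_assignments
  genes <- names(assignment)
  n <- length(genes)
  modules <- sort(unique(assignment[!is.na(assignment)]))
  factors <- matrix(stats::rnorm(length(modules) * n_samples),
                    nrow = length(modules))
  expr <- matrix(stats::rnorm(n * n_samples), nrow = n,
                 dimnames = list(genes, sprintf("S%03d", seq_len(n_samples))))
  for (m in modules) {
    rows <- which(assignment == m)
    noise <- matrix(stats::rnorm(length(rows) * n_samples, sd = config$noise_sd),
                    nrow = length(rows))
    expr[rows, ] <- matrix(factors[match(m, modules), ], nrow = length(rows),
                           ncol = n_samples, byrow = TRUE) + noise
  }
  expr
}

#' Simulate pathway gene sets
#'
#' Named sets with sizes inside `pathway_size_range`; a configurable
#' fraction of the sets is sampled with elevated odds for planted hub
#' genes, providing positive controls for [hypergeom_enrichment()].
#'
#' @param truth Planted truth (needs `hub_ids` and the gene universe via
#'   `target_degree`).
#' @param config The [synthetic_config()]; `hub_enriched_frac` and
#'   `hub_odds` control the planted enrichment.
#' @return Named list of character vectors (a gene-set collection); the
#'   attribute `"hub_enriched"` flags the positive-control sets. Pathway
#'   membership is also recorded in the returned attribute `"truth"`.
#' @export
simulate_pathway_sets <- function(truth, config) {
  if (config$n_pathways < 1) stop_bad("n_pathways must be >= 1")
  set.seed(config$seed + 4L)
  genes <- names(truth$target_degree)
  is_hub <- genes %in% truth$hub_ids
  sizes <- sample_from(seq(config$pathway_size_range[1], config$pathway_size_range[2]),
                       config$n_pathways, replace = TRUE)
  enriched <- stats::runif(config$n_pathways) < config$hub_enriched_frac
  sets <- vector("list", config$n_pathways)
  for (p in seq_len(config$n_pathways)) {
    w <- if (enriched[p]) 1 + (config$hub_odds - 1) * is_hub else rep(1, length(genes))
    sets[[p]] <- sort(sample(genes, sizes[p], prob = w))
  }
  names(sets) <- sprintf("PW%03d", seq_len(config$n_pathways))
  attr(sets, "hub_enriched") <- stats::setNames(enriched, names(sets))
  sets
}

#' Generate the full synthetic benchmark in one call
#'
#' Runs the network, annotation, module, expression and pathway generators
#' with the per-stage seed offsets derived from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @param n_samples Expression samples to simulate.
#' @return List: `network`, `truth`, `gene_table`, `expression`,
#'   `pathway_sets`.
#' @export
simulate_benchmark <- function(config = synthetic_config(), n_samples = 50) {
  net <- simulate_ppi_network(config)
  truth <- plant_modules(net$network, net$truth, config)
  gene_table <- simulate_gene_table(net$network, truth, config)
  expression <- simulate_expression(truth, n_samples, config)
  pathway_sets <- simulate_pathway_sets(truth, config)
  truth$pathway_membership <- pathway_sets
  list(network = net$network, truth = truth, gene_table = gene_table,
       expression = expression, pathway_sets = pathway_sets)
}
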