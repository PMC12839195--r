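#' MLDPP configuration
#'
#' Damping, iteration, and convergence parameters of the dynamic
#' perturbation propagation algorithm. Convergence requires all three
#' criteria simultaneously: L2 change below `tol_l2`, element-wise maximum
#' change below `tol_max`, and Spearman correlation between consecutive
#' states above `tol_corr`.
#'
#' @param alpha Damping parameter in (0,1); weight of the network term.
#' @param max_iter Iteration cap (failsafe).
#' @param horizon Reporting horizon: metrics are read at
#'   `min(converged_at, horizon)`.
#' @param tol_l2,tol_max,tol_corr Convergence tolerances.
#' @param stability_window Number of trailing iterations over which dynamic
#'   stability (an SD) is computed.
#' @return Object of class `mldpp_config`.
#' @export
mldpp_config <- function(alpha = 0.85, max_iter = 50, horizon = 25,
                         tol_l2 = 1e-6, tol_max = 1e-5, tol_corr = 0.9999,
                         stability_window = 5) {
  if (alpha <= 0 || alpha >= 1) stop_bad("alpha must lie in (0,1)")
  if (any(c(tol_l2, tol_max) <= 0)) stop_bad("tolerances must be positive")
  if (horizon > max_iter) stop_bad("horizon must not exceed max_iter")
  structure(list(alpha = alpha, max_iter = as.integer(max_iter),
                 horizon = as.integer(horizon), tol_l2 = tol_l2,
                 tol_max = tol_max, tol_corr = tol_corr,
                 stability_window = as.integer(stability_window)),
            class = "mldpp_config")
}

#' Symmetric degree-normalized adjacency
#'
#' `A_sym = D^(-1/2) W D^(-1/2)` where W is the confidence-weighted
#' adjacency and D its weighted-degree diagonal. Rows/columns of isolated
#' nodes are zero. The spectral radius is at most 1.
#'
#' @param network igraph network with `confidence` edge weights.
#' @return Sparse symmetric matrix (genes in `V(network)` order).
#' @export
normalized_adjacency <- function(network) {
  W <- weighted_adjacency(network)
  d <- Matrix::rowSums(W)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  A <- Matrix::Diagonal(x = inv_sqrt) %*% W %*% Matrix::Diagonal(x = inv_sqrt)
  dimnames(A) <- dimnames(W)
  A
}

#' Stratified initial perturbation vector
#'
#' Seeds the propagation by gene stratum: hub AND high-risk genes start at
#' 1.0, hubs without high risk at 0.8, high-risk non-hubs at 0.6, and all
#' remaining genes at a linear map of their degree onto \[0.1, 0.5\]
#' (minimum remaining degree -> 0.1, maximum -> 0.5; 0.3 for a degenerate
#' zero range).
#'
#' @param gene_table Gene annotation tibble (columns `symbol`,
#'   `risk_level`).
#' @param hubs [classify_hubs()] result.
#' @param network igraph network (defines gene order and degrees).
#' @return Named numeric vector p(0) in `V(network)` order.
#' @export
initialize_perturbation <- function(gene_table, hubs, network) {
  assert_network(network)
  genes <- igraph::V(network)$name
  risk <- gene_table$risk_level[match(genes, gene_table$symbol)]
  is_hub <- hubs$is_hub[match(genes, hubs$gene)]
  if (anyNA(risk) || anyNA(is_hub)) {
    stop_bad("every network gene needs a risk level and a hub label")
  }
  high <- risk == "high"
  p0 <- numeric(length(genes))
  p0[is_hub & high] <- 1.0
  p0[is_hub & !high] <- 0.8
  p0[!is_hub & high] <- 0.6
  rest <- !is_hub & !high
  if (any(rest)) {
    deg <- igraph::degree(network)[rest]
    rng <- range(deg)
    p0[rest] <- if (rng[1] == rng[2]) 0.3
                else 0.1 + 0.4 * (deg - rng[1]) / (rng[2] - rng[1])
  }
  stats::setNames(p0, genes)
}

#' Run the dynamic perturbation propagation (MLDPP)
#'
#' Iterates `p(t+1) = tanh(alpha * A_sym %*% p(t) + (1 - alpha) * p(0))`
#' until all three convergence criteria hold or `max_iter` is reached.
#' The hyperbolic tangent bounds every propagated state strictly inside
#' (-1, 1); the damping term retains the stratified initial state. The
#' full trajectory is retained.
#'
#' @param network igraph network.
#' @param p0 Initial perturbation vector (entries in \[0,1\], length =
#'   number of genes, `V(network)` order).
#' @param config [mldpp_config()].
#' @return Object of class `mldpp_run`: `states` ((T+1) x genes matrix,
#'   row 1 = p(0)), `converged_at` (iteration index or `NA`), `config`.
#' @export
run_mldpp <- function(network, p0, config = mldpp_config()) {
  assert_network(network)
  n <- igraph::vcount(network)
  if (length(p0) != n) stop_bad("p0 length (%d) != gene count (%d)", length(p0), n)
  if (any(p0 < 0 | p0 > 1)) stop_bad("p0 entries must lie in [0,1]")
  A <- normalized_adjacency(network)
  genes <- igraph::V(network)$name
  a <- config$alpha
  states <- matrix(NA_real_, nrow = config$max_iter + 1, ncol = n,
                   dimnames = list(NULL, genes))
  states[1, ] <- p0
  p <- p0
  converged_at <- NA_integer_
  for (t in seq_len(config$max_iter)) {
    pn <- tanh(a * as.numeric(A %*% p) + (1 - a) * p0)
    if (!all(is.finite(pn))) stop_bad("non-finite propagation state at iteration %d", t)
    states[t + 1, ] <- pn
    l2 <- sqrt(sum((pn - p)^2))
    mx <- max(abs(pn - p))
    rho <- suppressWarnings(stats::cor(pn, p, method = "spearman"))
    p <- pn
    if (l2 < config$tol_l2 && mx < config$tol_max &&
        !is.na(rho) && rho > config$tol_corr) {
      converged_at <- t
      break
    }
  }
  last <- if (is.na(converged_at)) config$max_iter else converged_at
  structure(list(states = states[seq_len(last + 1), , drop = FALSE],
                 converged_at = converged_at,
                 init = p0, config = config),
            class = "mldpp_run")
}

#' @export
print.mldpp_run <- function(x, ...) {
  T <- nrow(x$states) - 1
  cat(sprintf("MLDPP run: %d genes, %d iterations, %s\n",
              ncol(x$states), T,
              if (is.na(x$converged_at)) "not converged"
              else sprintf("converged at iteration %d", x$converged_at)))
  invisible(x)
}

#' Per-gene MLDPP metrics
#'
#' Reads the trajectory at `T* = min(converged_at, horizon)` and derives:
#' `final` = p(T*); `stability` = SD of p over the `stability_window`
#' trailing iterations up to T*; `gain` = final minus the static
#' perturbation score (default baseline) or minus the stratified seed with
#' `gain_baseline = "seed"`; `integrated_risk` = final x stability.
#'
#' @param run [run_mldpp()] result.
#' @param static_scores Tibble from [perturbation_scores()] (used as the
#'   gain baseline).
#' @param gain_baseline `"static"` (default) or `"seed"`.
#' @return Tibble: `gene`, `final`, `stability`, `gain`, `integrated_risk`.
#' @export
mldpp_metrics <- function(run, static_scores,
                          gain_baseline = c("static", "seed")) {
  gain_baseline <- match.arg(gain_baseline)
  stopifnot(inherits(run, "mldpp_run"))
  w <- run$config$stability_window
  Tn <- nrow(run$states) - 1
  Tstar <- min(if (is.na(run$converged_at)) Tn else run$converged_at,
               run$config$horizon, Tn)
  if (Tstar < w) stop_bad("trajectory shorter than the stability window")
  genes <- colnames(run$states)
  final <- run$states[Tstar + 1, ]
  window_rows <- (Tstar + 1 - w + 1):(Tstar + 1)
  stability <- apply(run$states[window_rows, , drop = FALSE], 2, stats::sd)
  base <- if (gain_baseline == "static") {
    static_scores$score[match(genes, static_scores$gene)]
  } else {
    run$init
  }
  tibble::tibble(
    gene = genes,
    final = as.numeric(final),
    stability = as.numeric(stability),
    gain = as.numeric(final - base),
    integrated_risk = as.numeric(final * stability)
  )
}

#' Comparator network propagators
#'
#' Standard single-channel diffusion baselines on the same weighted
#' network: `rwr` -- random walk with restart, iterating
#' `p <- (1-r) W_colnorm p + r p0`; `heat` -- the heat kernel
#' `exp(-t L) p0` with L the combinatorial Laplacian of the confidence
#' weights (dense eigendecomposition); `netprop` -- the linear damped
#' update `p <- alpha A_sym p + (1-alpha) p0` without the tanh saturation
#' (use binary high-risk seeds for the classical variant).
#'
#' @param network igraph network.
#' @param p0 Seed vector.
#' @param method One of `"rwr"`, `"heat"`, `"netprop"`.
#' @param restart RWR restart probability (default 0.15).
#' @param t_diffusion Heat diffusion time (default 1).
#' @param alpha Damping for `netprop` (default 0.85).
#' @param tol,max_iter Iteration controls for the iterative methods.
#' @return Tibble: `gene`, `score`.
#' @export
comparator_propagation <- function(network, p0,
                                   method = c("rwr", "heat", "netprop"),
                                   restart = 0.15, t_diffusion = 1,
                                   alpha = 0.85, tol = 1e-10, max_iter = 1000) {
  method <- match.arg(method)
  assert_network(network)
  n <- igraph::vcount(network)
  if (length(p0) != n) stop_bad("p0 length mismatch")
  genes <- igraph::V(network)$name
  W <- weighted_adjacency(network)
  score <- switch(method,
    rwr = {
      cs <- Matrix::colSums(W)
      P <- W %*% Matrix::Diagonal(x = ifelse(cs > 0, 1 / cs, 0))
      p <- p0
      for (i in seq_len(max_iter)) {
        pn <- (1 - restart) * as.numeric(P %*% p) + restart * p0
        if (sqrt(sum((pn - p)^2)) < tol) { p <- pn; break }
        p <- pn
      }
      p
    },
    heat = {
      L <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
      eig <- eigen(as.matrix(L), symmetric = TRUE)
      as.numeric(eig$vectors %*% (exp(-t_diffusion * eig$values) *
                                    crossprod(eig$vectors, p0)))
    },
    netprop = {
      A <- normalized_adjacency(network)
      p <- p0
      for (i in seq_len(max_iter)) {
        pn <- alpha * as.numeric(A %*% p) + (1 - alpha) * p0
        if (sqrt(sum((pn - p)^2)) < tol) { p <- pn; break }
        p <- pn
      }
      p
    }
  )
  tibble::tibble(gene = genes, score = score)
}

#' Steiger's Z for dependent correlations sharing one variable
#'
#' Tests whether r12 differs from r13 given the correlation r23 between
#' the two non-shared variables (Steiger 1980, using Fisher z transforms
#' and the mean correlation in the covariance term). Two-sided p from the
#' standard normal.
#'
#' @param r12,r13 The two correlations being compared (share variable 1).
#' @param r23 Correlation between variables 2 and 3.
#' @param n Sample size (> 3).
#' @return List with `Z` and `p`.
#' @export
steiger_z <- function(r12, r13, r23, n) {
  if (any(abs(c(r12, r13, r23)) >= 1)) {
    stop_bad("correlations must lie strictly inside (-1, 1)")
  }
  if (n <= 3) stop_bad("n must exceed 3")
  z12 <- atanh(r12); z13 <- atanh(r13)
  rbar <- (r12 + r13) / 2
  # covariance of the dependent correlations (Steiger's case A)
  num <- r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
  cov <- num / (1 - rbar^2)^2
  Z <- (z12 - z13) * sqrt((n - 3) / (2 - 2 * cov))
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)))
}

#' Damping-parameter sensitivity sweep
#'
#' Runs the full MLDPP at each candidate `alpha`, then reports the
#' Spearman correlation of final scores against the reference alpha and
#' the overlap of the top-`top_k` gene lists.
#'
#' @param network igraph network.
#' @param gene_table Gene annotations.
#' @param hubs [classify_hubs()] result.
#' @param alphas Candidate damping values (must contain `reference`).
#' @param reference Reference alpha (default 0.85).
#' @param top_k Size of the top-gene list (default 10).
#' @param config Base [mldpp_config()]; `alpha` is overridden per run.
#' @return Tibble: `alpha`, `spearman_vs_ref`, `top_overlap`; per-alpha
#'   final-score matrix in the `scores` attribute.
#' @export
alpha_sensitivity <- function(network, gene_table, hubs,
                              alphas = seq(0.5, 0.95, by = 0.05),
                              reference = 0.85, top_k = 10,
                              config = mldpp_config()) {
  if (!any(abs(alphas - reference) < 1e-9)) {
    stop_bad("reference alpha must be among the tested alphas")
  }
  if (any(alphas <= 0 | alphas >= 1)) stop_bad("alphas must lie in (0,1)")
  p0 <- initialize_perturbation(gene_table, hubs, network)
  stat <- perturbation_scores(network)
  finals <- purrr::map(alphas, function(a) {
    cfg <- config; cfg$alpha <- a
    run <- run_mldpp(network, p0, cfg)
    mldpp_metrics(run, stat)$final
  })
  genes <- igraph::V(network)$name
  mat <- do.call(cbind, finals)
  colnames(mat) <- sprintf("alpha_%.2f", alphas)
  rownames(mat) <- genes
  ref_idx <- which(abs(alphas - reference) < 1e-9)[1]
  ref <- mat[, ref_idx]
  top_ref <- genes[order(-ref)][seq_len(top_k)]
  out <- tibble::tibble(
    alpha = alphas,
    spearman_vs_ref = unname(apply(mat, 2, function(v) {
      stats::cor(v, ref, method = "spearman")
    })),
    top_overlap = unname(apply(mat, 2, function(v) {
      length(intersect(genes[order(-v)][seq_len(top_k)], top_ref))
    }))
  )
  attr(out, "scores") <- mat
  out
}
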