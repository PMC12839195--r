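#' Hypergeometric gene-set enrichment
#'
#' For each gene set, tests whether its overlap with the test set exceeds
#' the random-sampling expectation within the gene universe: exact
#' upper-tail hypergeometric p `P(X >= observed)`, expected count
#' `|set| * |test| / |universe|`, enrichment ratio observed/expected, and
#' BH-adjusted q across all sets tested together. Sets are intersected
#' with the universe before testing.
#'
#' @param test_set Character vector of test genes (subset of `universe`).
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector, the background gene universe.
#' @return Tibble of class `enrichment_result`: `set`, `set_size`,
#'   `observed`, `expected`, `ratio`, `p`, `q`.
#' @export
hypergeom_enrichment <- function(test_set, gene_sets, universe) {
  universe <- unique(universe)
  test_set <- unique(test_set)
  if (!length(universe)) stop_bad("empty universe")
  if (!length(test_set)) stop_bad("empty test set")
  extra <- setdiff(test_set, universe)
  if (length(extra)) stop_bad("test set contains genes outside the universe: %s",
                              paste(utils::head(extra, 3), collapse = ", "))
  N <- length(universe); n <- length(test_set)
  res <- purrr::imap_dfr(gene_sets, function(s, nm) {
    s <- intersect(unique(s), universe)
    K <- length(s)
    obs <- length(intersect(s, test_set))
    expected <- K * n / N
    p <- stats::phyper(obs - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set = nm, set_size = K, observed = obs,
                   expected = expected,
                   ratio = ifelse(expected > 0, obs / expected, NA_real_),
                   p = p)
  })
  res$q <- bh_fdr(res$p)
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Benjamini--Hochberg step-up adjusted p-values
#'
#' @param pvalues Numeric p-values in \[0,1\]; `NA`/`NaN` is an error.
#' @return q-values, order-preserving with the input.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues)) stop_bad("NA p-values are not allowed")
  if (any(pvalues < 0 | pvalues > 1)) stop_bad("p-values must lie in [0,1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p computed by summing hypergeometric point masses not
#' exceeding the observed mass (with the usual relative tolerance).
#' The odds ratio is the sample OR `ad/bc`; when a zero cell exists the
#' Haldane 0.5 correction is applied and flagged. The 95% CI is the Woolf
#' log interval.
#'
#' @param a,b,c,d Cell counts (`a` = both conditions, rows are condition
#'   1, columns condition 2).
#' @return List: `odds_ratio`, `ci95` (length 2), `p`, `corrected`
#'   (logical, Haldane correction applied).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_bad("cells must be nonnegative integers")
  }
  if (any(c(a + b, c + d, a + c, b + d) == 0)) stop_bad("zero margin")
  m <- a + c; n_col <- b + d; k <- a + b
  support <- max(0, k - n_col):min(k, m)
  dens <- stats::dhyper(support, m, n_col, k)
  obs <- stats::dhyper(a, m, n_col, k)
  p <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- cells[1] * cells[4] / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  list(odds_ratio = or, ci95 = ci, p = p, corrected = corrected)
}

#' Jaccard overlap network of gene sets
#'
#' Pairwise Jaccard indices `|A intersect B| / |A union B|`; pairs at or
#' above `min_jaccard` become weighted edges.
#'
#' @param gene_sets Named list (>= 2 sets).
#' @param min_jaccard Minimum Jaccard to keep an edge (default 0).
#' @return Tibble: `set_a`, `set_b`, `shared`, `union`, `jaccard`.
#' @export
jaccard_overlap_network <- function(gene_sets, min_jaccard = 0) {
  if (length(gene_sets) < 2) stop_bad("need at least 2 gene sets")
  nms <- names(gene_sets)
  pairs <- utils::combn(seq_along(gene_sets), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    A <- unique(gene_sets[[pairs[1, i]]]); B <- unique(gene_sets[[pairs[2, i]]])
    shared <- length(intersect(A, B)); uni <- length(union(A, B))
    tibble::tibble(set_a = nms[pairs[1, i]], set_b = nms[pairs[2, i]],
                   shared = shared, union = uni,
                   jaccard = ifelse(uni > 0, shared / uni, 0))
  })
  dplyr::filter(res, .data$jaccard >= min_jaccard)
}

#' Jaccard index of two gene sets
#'
#' @param a,b Character vectors.
#' @return `|a intersect b| / |a union b|`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Mann--Whitney U test with rank-biserial effect size
#'
#' U statistic for the first sample, two-sided p (exact enumeration when
#' both samples have at most 10 untied observations, tie-corrected normal
#' approximation otherwise), and effect size `r = |Z| / sqrt(n_x + n_y)`.
#'
#' @param x,y Numeric samples.
#' @return List: `U`, `p`, `effect_r`, `Z`, `method`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop_bad("both samples must be nonempty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  mu <- nx * ny / 2
  sigma <- sqrt(nx * ny / 12 * ((N + 1) - tie_term / (N * (N - 1))))
  Z <- if (sigma > 0) (U - mu) / sigma else 0
  exact <- nx <= 10 && ny <= 10 && tie_term == 0
  p <- if (exact) {
    lo <- min(U, nx * ny - U)
    min(1, 2 * stats::pwilcox(lo, nx, ny))
  } else {
    2 * stats::pnorm(-abs(Z))
  }
  list(U = U, p = min(1, p), effect_r = abs(Z) / sqrt(N), Z = Z,
       method = if (exact) "exact" else "normal")
}

#' Kruskal--Wallis with Dunn--Bonferroni post hoc comparisons
#'
#' Tie-corrected H and p (via `stats::kruskal.test`), the eta-squared
#' effect size `(H - k + 1)/(n - k)`, and all pairwise Dunn z statistics
#' with Bonferroni-adjusted p-values.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return List: `H`, `p`, `eta_squared`, `pairwise` (tibble).
#' @export
kruskal_dunn <- function(groups) {
  if (length(groups) < 2) stop_bad("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop_bad("every group needs at least 2 members")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = names(groups))
  kt <- stats::kruskal.test(values, labels)
  H <- unname(kt$statistic)
  k <- length(groups); n <- length(values)
  eta_sq <- (H - k + 1) / (n - k)

  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_ranks <- tapply(r, labels, mean)
  sizes <- tapply(r, labels, length)
  pairs <- utils::combn(names(groups), 2)
  n_comp <- ncol(pairs)
  pairwise <- purrr::map_dfr(seq_len(n_comp), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    z <- (mean_ranks[[g1]] - mean_ranks[[g2]]) / se
    tibble::tibble(group_a = g1, group_b = g2, z = z,
                   p = 2 * stats::pnorm(-abs(z)),
                   p_adjusted = min(1, 2 * stats::pnorm(-abs(z)) * n_comp))
  })
  list(H = H, p = kt$p.value, eta_squared = eta_sq, pairwise = pairwise)
}

#' Seed-deterministic permutation p-value
#'
#' Empirical add-one estimator
#' `p = (1 + #\{permuted >= observed\}) / (1 + n_perm)` for a statistic
#' under random relabeling. `statistic_fn` receives the data and must be a
#' pure function; `permute_fn` produces a permuted copy of the data.
#'
#' @param statistic_fn Function `data -> numeric scalar`.
#' @param data The observed data object.
#' @param permute_fn Function `data -> permuted data` (uses the RNG).
#' @param n_perm Number of permutations (warning below 100).
#' @param seed RNG seed.
#' @return List: `observed`, `p`, `n_perm`.
#' @export
permutation_pvalue <- function(statistic_fn, data, permute_fn,
                               n_perm = 10000, seed = 1L) {
  if (n_perm < 100) warning("n_perm < 100: p-value resolution is very coarse",
                            call. = FALSE)
  observed <- statistic_fn(data)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (statistic_fn(permute_fn(data)) >= observed) exceed <- exceed + 1L
  }
  list(observed = observed, p = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}
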