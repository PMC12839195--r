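toy_hypergraph <- function() {
  assemble_hypergraph(
    list(clique = list(c("a", "b", "c"), c("c", "d", "e")),
         coexpression = list(c("a", "d", "e"))),
    nodes = letters[1:5])
}

test_that("feature matrices standardize and select the documented columns", {
  bench <- shared_bench()
  cent <- centrality_profile(bench$network)
  sc <- perturbation_scores(bench$network)
  hubs <- classify_hubs(sc)
  p0 <- initialize_perturbation(bench$gene_table, hubs, bench$network)
  met <- mldpp_metrics(run_mldpp(bench$network, p0), sc)

  fm <- build_feature_matrix(cent, met, bench$gene_table, sc, "topology7")
  expect_equal(colnames(fm$X),
               c("degree_centrality", "betweenness", "closeness",
                 "clustering_coef", "perturbation_score", "mldpp_final",
                 "dynamic_stability"))
  expect_true(all(abs(colMeans(fm$X)) < 1e-9))
  expect_true(all(abs(apply(fm$X, 2, stats::sd)[!fm$constant] - 1) < 1e-9))

  fm5 <- build_feature_matrix(cent, NULL, bench$gene_table, NULL,
                              "hub_independent5")
  expect_false(any(grepl("centrality|betweenness|closeness|degree",
                         colnames(fm5$X))))
  expect_equal(ncol(fm5$X), 5)

  fm3 <- build_feature_matrix(cent, NULL, bench$gene_table, NULL,
                              "hub_independent3")
  expect_equal(colnames(fm3$X),
               c("clustering_coef", "panel_member", "log_degree"))
})

test_that("constant feature columns are flagged and left unscaled", {
  cent <- centrality_profile(triangle_graph())
  gt <- tibble::tibble(symbol = c("A", "B", "C"), category = "1",
                       risk_level = "high", constraint = 0.5,
                       gene_length_kb = c(1, 2, 3),
                       brain_expression = c(0, 1, 2), pathway_count = 1:3,
                       druggability = 0.5)
  fm <- build_feature_matrix(cent, NULL, gt, NULL, "hub_independent5")
  expect_true(fm$constant[["category_score"]])
  expect_equal(unique(fm$X[, "category_score"]), 0)
})

test_that("forward pass matches a loop-built dense propagation oracle", {
  hg <- toy_hypergraph()
  set.seed(7)
  X <- matrix(stats::rnorm(5 * 3), 5, 3, dimnames = list(hg$nodes, NULL))
  params <- hgnn_init(3, dims = c(4, 3, 2), dropout = 0, seed = 2)
  fw <- hgnn_forward(hg, X, params, training = FALSE)

  # dense operator built entry-wise from first principles
  P <- matrix(0, 5, 5)
  for (e in seq_along(hg$edges)) {
    m <- match(hg$edges[[e]], hg$nodes)
    for (i in m) for (j in m) {
      P[i, j] <- P[i, j] + hg$weight[e] / hg$De[e] /
        sqrt(hg$Dv[i] * hg$Dv[j])
    }
  }
  expect_equal(fw$conv[[1]], P %*% X %*% params$layers[[1]]$Theta,
               tolerance = 1e-12)
})

test_that("evaluation mode is deterministic and dropout-0 training matches it", {
  hg <- toy_hypergraph()
  set.seed(1)
  X <- matrix(stats::rnorm(5 * 3), 5, 3, dimnames = list(hg$nodes, NULL))
  params <- hgnn_init(3, seed = 4, dropout = 0)
  e1 <- hgnn_forward(hg, X, params, training = FALSE)$embedding
  e2 <- hgnn_forward(hg, X, params, training = FALSE)$embedding
  expect_identical(e1, e2)
  # with dropout 0 the only train/eval difference is the batch-norm source
  et <- hgnn_forward(hg, X, params, training = TRUE)$embedding
  et2 <- hgnn_forward(hg, X, params, training = TRUE)$embedding
  expect_identical(et, et2)
})

test_that("contrastive loss obeys the margin geometry", {
  # satisfied margins -> zero loss
  E <- rbind(c(0, 0), c(0.2, 0), c(5, 0), c(5.2, 0))
  hub <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(contrastive_loss(E, hub), 0)

  # one hub pair at distance 1: (1 - 0.5)^2 = 0.25
  E2 <- rbind(c(0, 0), c(1, 0), c(10, 0))
  expect_equal(contrastive_loss(E2, c(TRUE, TRUE, FALSE)), 0.25)

  # one cross pair at distance 1: (1.5 - 1)^2 = 0.25
  E3 <- rbind(c(0, 0), c(1, 0))
  expect_equal(contrastive_loss(E3, c(TRUE, FALSE)), 0.25)

  expect_error(contrastive_loss(E2, c(TRUE, TRUE, TRUE)), "non-hub")

  # property: zero iff every pair satisfies its margin
  set.seed(23)
  for (i in 1:20) {
    E <- matrix(stats::rnorm(12), 6, 2)
    hub <- sample(c(TRUE, FALSE), 6, replace = TRUE)
    if (!any(hub) || all(hub)) next
    d <- as.matrix(stats::dist(E))
    ok <- TRUE
    for (a in 1:5) for (b in (a + 1):6) {
      if (hub[a] && hub[b] && d[a, b] > 0.5) ok <- FALSE
      if (xor(hub[a], hub[b]) && d[a, b] < 1.5) ok <- FALSE
    }
    expect_equal(contrastive_loss(E, hub) == 0, ok)
  }
})

test_that("backpropagated gradients match finite differences", {
  hg <- toy_hypergraph()
  set.seed(2)
  X <- matrix(stats::rnorm(5 * 4), 5, 4, dimnames = list(hg$nodes, NULL))
  params <- hgnn_init(4, dims = c(6, 5, 3), dropout = 0, seed = 3)
  P <- netperturb:::hypergraph_operator(hg)
  hub <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  idx <- 1:5
  an <- netperturb:::hgnn_loss_grads(P, X, params, hub, idx)
  loss_at <- function(pp) {
    fw <- netperturb:::hgnn_forward_cache(P, X, pp, dropout = FALSE,
                                          bn = "batch")
    contrastive_loss(fw$embedding[idx, , drop = FALSE], hub[idx])
  }
  h <- 1e-6
  worst <- 0
  for (l in 1:3) {
    for (what in c("Theta", "bn_gamma", "bn_beta")) {
      if (l == 3 && what != "Theta") next
      M <- params$layers[[l]][[what]]
      g_an <- switch(what, Theta = an$grads[[l]]$Theta,
                     bn_gamma = an$grads[[l]]$gamma,
                     bn_beta = an$grads[[l]]$beta)
      probe <- seq_len(min(8, length(M)))
      for (i in probe) {
        pp <- params
        pp$layers[[l]][[what]][i] <- M[i] + h
        up <- loss_at(pp)
        pp$layers[[l]][[what]][i] <- M[i] - h
        dn <- loss_at(pp)
        fd <- (up - dn) / (2 * h)
        rel <- abs(fd - g_an[i]) / max(abs(fd), abs(g_an[i]), 1e-8)
        worst <- max(worst, rel)
      }
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("training is seed-deterministic and separates planted classes", {
  bench <- shared_bench()
  sc <- perturbation_scores(bench$network)
  hubs <- classify_hubs(sc)
  p0 <- initialize_perturbation(bench$gene_table, hubs, bench$network)
  met <- mldpp_metrics(run_mldpp(bench$network, p0), sc)
  cent <- centrality_profile(bench$network)
  fm <- build_feature_matrix(cent, met, bench$gene_table, sc, "topology7")
  src <- list(clique = clique_hyperedges(bench$network),
              reactome_pathway = pathway_hyperedges(
                bench$pathway_sets, igraph::V(bench$network)$name))
  hg <- assemble_hypergraph(src, igraph::V(bench$network)$name)

  tc <- train_config(max_epochs = 3, patience = 2, seed = 9)
  f1 <- train_hgnn(hg, fm$X, hubs$is_hub, tc)
  f2 <- train_hgnn(hg, fm$X, hubs$is_hub, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$embedding, f2$embedding)
})

test_that("k-means clustering recovers trivial and well-separated structure", {
  pts <- matrix(c(0, 0, 10, 10), 4, 1)
  rownames(pts) <- paste0("p", 1:4)
  cl <- kmeans_clusters(pts, k = 2, n_init = 5, seed = 1)
  expect_equal(attr(cl, "inertia"), 0)
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_false(cl$cluster[1] == cl$cluster[3])

  cl_n <- kmeans_clusters(pts, k = 4, n_init = 5, seed = 1)
  expect_equal(attr(cl_n, "inertia"), 0)
  expect_error(kmeans_clusters(pts, k = 1), ">= 2")
  expect_error(kmeans_clusters(pts, k = 9), "exceeds")

  set.seed(19)
  blobs <- do.call(rbind, lapply(0:4, function(c2) {
    matrix(stats::rnorm(40, mean = 10 * c2), 20, 2)
  }))
  rownames(blobs) <- sprintf("b%03d", 1:100)
  clb <- kmeans_clusters(blobs, k = 5, n_init = 20, seed = 7)
  expect_equal(adjusted_rand_index(clb$cluster, rep(1:5, each = 20)), 1)
})

test_that("cluster quality indices match hand and textbook computations", {
  X <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  q <- cluster_quality(X, c(1, 1, 2, 2))
  a <- 1
  b <- mean(c(10, sqrt(101)))
  expect_equal(q$silhouette, (b - a) / b, tolerance = 1e-9)
  expect_equal(round(q$silhouette, 3), 0.900)

  set.seed(26)
  Y <- matrix(stats::rnorm(60 * 3), 60, 3)
  cl <- sample(1:3, 60, replace = TRUE)
  mine <- cluster_quality(Y, cl)
  oracle <- oracle_cluster_indices(Y, cl)
  expect_equal(mine$silhouette, oracle$silhouette, tolerance = 1e-7)
  expect_equal(mine$calinski_harabasz, oracle$ch, tolerance = 1e-7)
  expect_equal(mine$davies_bouldin, oracle$db, tolerance = 1e-7)
  expect_error(cluster_quality(Y, rep(1, 60)), "2 clusters")
})

test_that("silhouette agrees with the cluster package on random data", {
  skip_if_not_installed("cluster")
  set.seed(27)
  Y <- matrix(stats::rnorm(40 * 2), 40, 2)
  cl <- sample(1:4, 40, replace = TRUE)
  ref <- mean(cluster::silhouette(cl, stats::dist(Y))[, 3])
  expect_equal(cluster_quality(Y, cl)$silhouette, ref, tolerance = 1e-7)
})

test_that("PCA projection is deterministic with explained variance accounting", {
  line <- cbind(1:10, 2 * (1:10))
  rownames(line) <- paste0("g", 1:10)
  pr <- project_2d(line, "pca")
  ev <- attr(pr, "explained_variance")
  expect_equal(ev[1], 1, tolerance = 1e-12)
  expect_lte(sum(ev), 1 + 1e-12)

  set.seed(28)
  M <- matrix(stats::rnorm(30 * 4), 30, 4)
  rownames(M) <- sprintf("m%02d", 1:30)
  p1 <- project_2d(M, "pca")
  p2 <- project_2d(M, "pca")
  expect_identical(p1, p2)
  expect_error(project_2d(M[1:2, ], "pca"), "at least 3")
})

test_that("t-SNE respects the perplexity precondition and returns coordinates", {
  set.seed(29)
  M <- matrix(stats::rnorm(45 * 3), 45, 3)
  rownames(M) <- sprintf("m%02d", 1:45)
  expect_error(project_2d(M, "tsne", perplexity = 20), "perplexity")
  out <- project_2d(M, "tsne", perplexity = 8, n_iter = 60, seed = 1)
  expect_equal(dim(out), c(45L, 3L))
  expect_true(all(is.finite(out$dim1)))
})

test_that("clustering comparison reports jaccard, permutation p, ARI and Fisher", {
  genes <- sprintf("g%02d", 1:40)
  a <- tibble::tibble(gene = genes, cluster = rep(1:4, each = 10))
  res_same <- compare_clusterings(a, a, focus_set = genes[1:10],
                                  n_perm = 200, seed = 1)
  expect_equal(res_same$jaccard, 1)
  expect_equal(res_same$adjusted_rand, 1)
  expect_lt(res_same$perm_p, 0.05)

  # two 10-member focus clusters sharing 8 genes -> 8 / 12
  b <- a
  b$cluster[9:10] <- 2
  b$cluster[c(11, 12)] <- 1
  res <- compare_clusterings(a, b, focus_set = genes[1:10],
                             n_perm = 200, seed = 1)
  expect_equal(res$jaccard, 8 / 12, tolerance = 1e-12)
  expect_equal(round(res$jaccard, 2), 0.67)

  expect_error(compare_clusterings(a, a, character(0)), "empty")

  set.seed(9)
  big <- tibble::tibble(gene = sprintf("x%04d", 1:1000),
                        cluster = rep(1:5, each = 200))
  shuffled <- tibble::tibble(gene = big$gene, cluster = sample(big$cluster))
  ari <- compare_clusterings(big, shuffled, focus_set = big$gene[1:10],
                             n_perm = 50, seed = 2)$adjusted_rand
  expect_lt(abs(ari), 0.05)
})

test_that("adjusted Rand agrees with mclust", {
  skip_if_not_installed("mclust")
  set.seed(33)
  for (i in 1:10) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- sample(1:3, 50, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 unname(mclust::adjustedRandIndex(a, b)), tolerance = 1e-12)
  }
})
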