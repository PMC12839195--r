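edgeless_network <- function(n = 3) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- letters[seq_len(n)]
  igraph::set_edge_attr(g, "confidence", value = numeric(0))
}

two_node_network <- function(w = 0.9) {
  toy_network(list("a", "b"), confidence = w)
}

test_that("normalized adjacency has unit off-diagonal for a single edge and bounded spectrum", {
  A <- as.matrix(normalized_adjacency(two_node_network(0.37)))
  expect_equal(A, matrix(c(0, 1, 1, 0), 2,
                         dimnames = list(c("a", "b"), c("a", "b"))))
  iso <- toy_network(list("a", "b"), confidence = 0.8,
                     vertices = data.frame(name = c("a", "b", "z")))
  Ai <- as.matrix(normalized_adjacency(iso))
  expect_equal(Ai["z", ], c(a = 0, b = 0, z = 0))

  set.seed(10)
  g <- random_toy_graph(10)
  igraph::E(g)$confidence <- stats::runif(igraph::ecount(g), 0.7, 1)
  ev <- eigen(as.matrix(normalized_adjacency(g)), symmetric = TRUE,
              only.values = TRUE)$values
  expect_lt(max(abs(ev)), 1 + 1e-12)
})

test_that("stratified initialization follows the four-tier rule", {
  bench <- shared_bench()
  hubs <- classify_hubs(perturbation_scores(bench$network))
  p0 <- initialize_perturbation(bench$gene_table, hubs, bench$network)
  genes <- igraph::V(bench$network)$name
  risk <- bench$gene_table$risk_level[match(genes, bench$gene_table$symbol)]
  is_hub <- hubs$is_hub[match(genes, hubs$gene)]
  expect_true(all(p0[is_hub & risk == "high"] == 1.0))
  expect_true(all(p0[is_hub & risk != "high"] == 0.8))
  expect_true(all(p0[!is_hub & risk == "high"] == 0.6))
  rest <- p0[!is_hub & risk != "high"]
  expect_true(all(rest >= 0.1 - 1e-12 & rest <= 0.5 + 1e-12))
  deg <- igraph::degree(bench$network)[!is_hub & risk != "high"]
  expect_equal(unname(rest[which.min(deg)]), 0.1)
  expect_equal(unname(rest[which.max(deg)]), 0.5)
})

test_that("edgeless graph reaches tanh((1-alpha) p0) immediately and converges by 2", {
  r <- run_mldpp(edgeless_network(), c(1, 0, 0))
  expect_equal(unname(r$states[2, ]), tanh(0.15 * c(1, 0, 0)))
  expect_equal(r$converged_at, 2L)
})

test_that("two-node network converges to the scalar fixed point", {
  cfg <- mldpp_config(max_iter = 300, horizon = 300)
  r <- run_mldpp(two_node_network(), c(1, 1), cfg)
  x <- 1
  for (i in 1:1000) x <- tanh(0.85 * x + 0.15)
  expect_equal(unname(r$states[nrow(r$states), ]), c(x, x), tolerance = 1e-6)
})

test_that("propagated states stay strictly inside (-1, 1)", {
  bench <- shared_bench()
  set.seed(6)
  p0 <- stats::runif(igraph::vcount(bench$network))
  r <- run_mldpp(bench$network, p0)
  body <- r$states[-1, ]
  expect_true(all(body > -1 & body < 1))
})

test_that("trajectories are deterministic and permutation-equivariant", {
  bench <- shared_bench()
  set.seed(3)
  p0 <- stats::runif(igraph::vcount(bench$network))
  r1 <- run_mldpp(bench$network, p0)
  r2 <- run_mldpp(bench$network, p0)
  expect_identical(r1$states, r2$states)

  perm <- sample(igraph::vcount(bench$network))
  gperm <- igraph::permute(bench$network, perm)
  p0_perm <- stats::setNames(numeric(length(p0)), igraph::V(gperm)$name)
  p0_perm[igraph::V(bench$network)$name] <- p0
  r3 <- run_mldpp(gperm, p0_perm)
  expect_equal(r3$states[, colnames(r1$states)], r1$states,
               tolerance = 1e-12)
})

test_that("metrics derive final, stability, gain, and integrated risk correctly", {
  bench <- shared_bench()
  sc <- perturbation_scores(bench$network)
  hubs <- classify_hubs(sc)
  p0 <- initialize_perturbation(bench$gene_table, hubs, bench$network)
  r <- run_mldpp(bench$network, p0)
  m <- mldpp_metrics(r, sc)
  expect_equal(m$integrated_risk, m$final * m$stability, tolerance = 1e-14)
  expect_true(all(m$stability >= 0))
  Tstar <- min(r$converged_at, r$config$horizon, nrow(r$states) - 1)
  expect_equal(m$final, unname(r$states[Tstar + 1, ]))

  # constant trajectory: stability and integrated risk are exactly zero
  rc <- run_mldpp(edgeless_network(), c(0, 0, 0),
                  mldpp_config(max_iter = 10, horizon = 10))
  sc0 <- tibble::tibble(gene = letters[1:3], score = 0)
  mc <- mldpp_metrics(rc, sc0)
  expect_equal(mc$stability, rep(0, 3))
  expect_equal(mc$integrated_risk, rep(0, 3))
  expect_error(
    mldpp_metrics(structure(list(states = rc$states[1:2, ],
                                 converged_at = NA,
                                 config = mldpp_config()),
                            class = "mldpp_run"), sc0),
    "window")
})

test_that("published group means reproduce the printed gain and integrated risk", {
  # gain = final - static baseline; integrated risk = final x stability
  # (agreement to within the rounding of the printed group means)
  expect_equal(0.4394 - 0.092, 0.3476, tolerance = 1e-3)
  expect_equal(0.4394 * 0.127, 0.055, tolerance = 2e-2)
  expect_equal(0.3097 - 0.020, 0.2902, tolerance = 2e-3)
})

test_that("planted hubs end with higher MLDPP scores than non-hubs", {
  bench <- shared_bench()
  sc <- perturbation_scores(bench$network)
  hubs <- classify_hubs(sc)
  p0 <- initialize_perturbation(bench$gene_table, hubs, bench$network)
  m <- mldpp_metrics(run_mldpp(bench$network, p0), sc)
  is_hub <- hubs$is_hub[match(m$gene, hubs$gene)]
  wt <- stats::wilcox.test(m$final[is_hub], m$final[!is_hub],
                           alternative = "greater")
  expect_lt(wt$p.value, 1e-3)
})

test_that("comparator propagators honour their boundary parameters", {
  bench <- shared_bench()
  set.seed(5)
  p0 <- stats::runif(igraph::vcount(bench$network))
  expect_equal(comparator_propagation(bench$network, p0, "rwr",
                                      restart = 1)$score, p0)
  expect_equal(comparator_propagation(bench$network, p0, "heat",
                                      t_diffusion = 0)$score, p0,
               tolerance = 1e-9)
  expect_error(comparator_propagation(bench$network, p0, "walktrap"))
})

test_that("two-node RWR matches the dense linear-system oracle", {
  g <- two_node_network(0.8)
  p <- comparator_propagation(g, c(1, 0), "rwr", restart = 0.15)
  Pcol <- matrix(c(0, 1, 1, 0), 2)  # column-normalized weights
  oracle <- solve(diag(2) - 0.85 * Pcol, 0.15 * c(1, 0))
  expect_equal(p$score, oracle, tolerance = 1e-8)
})

test_that("Steiger's Z matches an independently coded formula", {
  expect_equal(steiger_z(0.5, 0.5, 0.3, 100)$Z, 0)
  expect_equal(steiger_z(0.5, 0.5, 0.3, 100)$p, 1)
  z <- steiger_z(0.68, 0.45, 0.6, 893)
  expect_equal(z$Z, oracle_steiger_z(0.68, 0.45, 0.6, 893), tolerance = 1e-10)
  expect_true(is.finite(steiger_z(0.3, -0.2, 0.1, 4)$Z))
  expect_error(steiger_z(1, 0.5, 0.5, 10), "strictly inside")
})

test_that("alpha sensitivity is exact at the reference and errors off-grid", {
  bench <- shared_bench()
  hubs <- classify_hubs(perturbation_scores(bench$network))
  sens <- alpha_sensitivity(bench$network, bench$gene_table, hubs,
                            alphas = c(0.75, 0.85), reference = 0.85,
                            config = mldpp_config(max_iter = 30, horizon = 25))
  ref <- sens[abs(sens$alpha - 0.85) < 1e-9, ]
  expect_equal(ref$spearman_vs_ref, 1)
  expect_equal(ref$top_overlap, 10)
  expect_error(
    alpha_sensitivity(bench$network, bench$gene_table, hubs,
                      alphas = c(0.7, 0.8), reference = 0.85),
    "reference")
})
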