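test_that("maximal cliques follow the maximal convention", {
  expect_equal(clique_hyperedges(triangle_graph()), list(c("A", "B", "C")))

  k4 <- toy_network(list(c("A", "A", "A", "B", "B", "C"),
                         c("B", "C", "D", "C", "D", "D")))
  expect_equal(clique_hyperedges(k4), list(c("A", "B", "C", "D")))

  expect_length(clique_hyperedges(path_graph()), 0)
})

test_that("clique enumeration agrees with brute force on random graphs", {
  set.seed(17)
  for (i in 1:40) {
    g <- random_toy_graph(sample(5:11, 1), p = 0.5)
    if (is.null(g)) next
    mine <- clique_hyperedges(g, min_size = 3)
    oracle <- brute_maximal_cliques(g, min_size = 3)
    canon <- function(l) sort(vapply(l, paste, character(1), collapse = "|"))
    expect_identical(canon(mine), canon(oracle))
  }
})

test_that("co-expression hyperedges recover planted modules and reject noise", {
  ident <- matrix(rep(stats::rnorm(30), 3), nrow = 3, byrow = TRUE,
                  dimnames = list(c("g1", "g2", "g3"), NULL))
  expect_equal(coexpression_hyperedges(ident), list(c("g1", "g2", "g3")))

  set.seed(21)
  noise <- matrix(stats::rnorm(20 * 1000), nrow = 20,
                  dimnames = list(sprintf("n%02d", 1:20), NULL))
  expect_length(coexpression_hyperedges(noise), 0)

  cfg <- synthetic_config(n_genes = 80, n_modules = 2,
                          module_size_range = c(4, 4), seed = 3)
  net <- simulate_ppi_network(cfg)
  truth <- plant_modules(net$network, net$truth, cfg)
  expr <- simulate_expression(truth, 60, cfg)
  he <- coexpression_hyperedges(expr)
  planted <- lapply(split(names(truth$module_assignments),
                          truth$module_assignments), sort)
  canon <- function(l) sort(vapply(l, paste, character(1), collapse = "|"))
  expect_identical(canon(he), canon(unname(planted)))

  const <- rbind(ident, flat = rep(1, 30))
  expect_warning(coexpression_hyperedges(const), "constant")
})

test_that("hypergraph assembly dedupes, validates, and builds incidence", {
  tri <- list(c("A", "B", "C"))
  hg <- assemble_hypergraph(list(clique = tri, reactome_pathway = tri),
                            nodes = c("A", "B", "C", "D"))
  expect_length(hg$edges, 1)
  expect_equal(hg$weight, 2)               # duplicate weights summed
  expect_equal(hg$provenance, "clique")    # first provenance retained
  expect_equal(Matrix::rowSums(hg$H)[["D"]], 0)  # isolated node kept

  expect_error(assemble_hypergraph(list(clique = list(c("A", "X", "Y"))),
                                   nodes = c("A", "B", "C")), "unknown gene")
  expect_error(assemble_hypergraph(list(clique = list(c("A", "B"))),
                                   nodes = c("A", "B", "C")), "cardinality")
  expect_error(assemble_hypergraph(list(clique = list()), nodes = "A"),
               "nonempty")
})

test_that("incidence column sums equal hyperedge sizes on assembled hypergraphs", {
  bench <- shared_bench()
  src <- list(clique = clique_hyperedges(bench$network),
              reactome_pathway = pathway_hyperedges(
                bench$pathway_sets, igraph::V(bench$network)$name))
  hg <- assemble_hypergraph(src, igraph::V(bench$network)$name)
  expect_equal(unname(Matrix::colSums(hg$H)), as.numeric(hg$De))
  expect_equal(as.numeric(hg$H %*% hg$weight), hg$Dv)
})

test_that("hypergraph Laplacian matches hand linear algebra and stays PSD", {
  hg2 <- assemble_hypergraph(list(clique = list(c("a", "b"))),
                             nodes = c("a", "b"), min_size = 2)
  L <- hypergraph_laplacian(hg2)
  expect_equal(unname(L), matrix(c(0.5, -0.5, -0.5, 0.5), 2))
  expect_equal(sort(eigen(L, only.values = TRUE)$values), c(0, 1),
               tolerance = 1e-12)

  disj <- assemble_hypergraph(
    list(clique = list(c("a", "b", "c"), c("d", "e", "f"))),
    nodes = letters[1:6])
  ev <- eigen(hypergraph_laplacian(disj), symmetric = TRUE,
              only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-10), 2)   # one null direction per block

  set.seed(9)
  for (i in 1:10) {
    nodes <- sprintf("n%02d", 1:8)
    edges <- lapply(1:4, function(e) sample(nodes, sample(3:5, 1)))
    hg <- assemble_hypergraph(list(clique = edges), nodes)
    ev <- eigen(hypergraph_laplacian(hg), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), -1e-12)
    expect_lt(abs(min(ev)), 1e-10)
  }
})

test_that("spectral communities separate disconnected blocks exactly", {
  disj <- assemble_hypergraph(
    list(clique = list(c("a", "b", "c"), c("d", "e", "f"))),
    nodes = letters[1:6])
  com <- spectral_communities(disj, k = 2, seed = 1)
  lab <- stats::setNames(com$community, com$gene)
  expect_equal(length(unique(lab[c("a", "b", "c")])), 1)
  expect_equal(length(unique(lab[c("d", "e", "f")])), 1)
  expect_false(lab[["a"]] == lab[["d"]])

  all_own <- spectral_communities(disj, k = 6, seed = 1)
  expect_equal(sort(unique(all_own$community)), 1:6)
  expect_error(spectral_communities(disj, k = 7), "exceeds")
  expect_error(spectral_communities(disj, k = 1), ">= 2")
})

test_that("planted three-block hypergraphs are recovered by spectral clustering", {
  set.seed(12)
  aris <- vapply(1:10, function(s) {
    nodes <- sprintf("n%02d", 1:30)
    blocks <- split(nodes, rep(1:3, each = 10))
    edges <- unlist(lapply(blocks, function(b) {
      # cover every block member, then add random within-block hyperedges
      c(list(b[1:4], b[4:7], b[7:10]),
        lapply(1:3, function(i) sample(b, 4)))
    }), recursive = FALSE)
    hg <- assemble_hypergraph(list(clique = unname(edges)), nodes)
    com <- spectral_communities(hg, k = 3, seed = s)
    truth <- rep(1:3, each = 10)
    adjusted_rand_index(com$community, truth)
  }, numeric(1))
  expect_gt(mean(aris), 0.9)
})

test_that("module cohesion follows the three-factor product", {
  nodes <- c("A", "B", "C", "D")
  # 4-gene module, 4 of 6 possible PPI edges present
  ppi <- toy_network(list(c("A", "A", "B", "C"), c("B", "C", "C", "D")))
  hg <- assemble_hypergraph(list(clique = list(nodes)), nodes)
  scores <- tibble::tibble(gene = nodes, score = c(1.0, 0.8, 0.4, 0.2))
  # normalized mean = mean(0.6)/1.0; 2 of 4 hubs; density 4/6
  hubs <- tibble::tibble(gene = nodes, score = scores$score,
                         is_hub = c(TRUE, TRUE, FALSE, FALSE))
  coh <- module_cohesion(hg, scores, hubs, ppi)
  expect_equal(coh$normalized_mean_perturbation, 0.6)
  expect_equal(coh$hub_fraction, 0.5)
  expect_equal(coh$internal_density, 4 / 6)
  expect_equal(coh$cohesion, 0.6 * 0.5 * 4 / 6, tolerance = 1e-12)

  # all-hub clique of top scorers -> cohesion 1; zero hubs -> cohesion 0
  tri <- toy_network(list(c("A", "B", "A"), c("B", "C", "C")))
  hg3 <- assemble_hypergraph(list(clique = list(c("A", "B", "C"))),
                             c("A", "B", "C"))
  s3 <- tibble::tibble(gene = c("A", "B", "C"), score = c(1, 1, 1))
  h3 <- tibble::tibble(gene = c("A", "B", "C"), is_hub = rep(TRUE, 3))
  expect_equal(module_cohesion(hg3, s3, h3, tri)$cohesion, 1)
  h0 <- tibble::tibble(gene = c("A", "B", "C"), is_hub = rep(FALSE, 3))
  expect_equal(module_cohesion(hg3, s3, h0, tri)$cohesion, 0)
})

test_that("hypergraph modularity reproduces closed forms and favours structure", {
  hg2 <- assemble_hypergraph(
    list(clique = list(c("a", "b", "c"), c("d", "e", "f"))),
    nodes = letters[1:6])
  one <- tibble::tibble(gene = letters[1:6], community = 1)
  expect_equal(hypergraph_modularity(hg2, one), 0)
  two <- tibble::tibble(gene = letters[1:6], community = rep(1:2, each = 3))
  expect_equal(hypergraph_modularity(hg2, two), 0.5)
  expect_error(hypergraph_modularity(hg2, one[0, ]), "empty")

  set.seed(30)
  good <- hypergraph_modularity(hg2, two)
  rand <- replicate(20, {
    hypergraph_modularity(hg2, tibble::tibble(gene = letters[1:6],
                                              community = sample(1:2, 6,
                                                                 TRUE)))
  })
  expect_true(all(rand <= good + 1e-12))
})

test_that("multi-way statistic counts covered pairs beyond the PPI edges", {
  nodes <- c("A", "B", "C", "D")
  ppi <- toy_network(list(c("A", "A"), c("B", "C")))
  hg <- assemble_hypergraph(list(reactome_pathway = list(nodes)), nodes)
  s <- hypergraph_summary(hg, ppi)
  expect_equal(s$pair_slots, 6)
  expect_equal(s$covered_pairs, 6)
  expect_equal(s$pairs_already_present, 2)
  expect_equal(s$multiway_relationships, 4)
  expect_equal(s$multiway_gain_pct, 100 * 4 / 2)
})
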