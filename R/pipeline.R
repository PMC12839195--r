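#' Full-pipeline configuration
#'
#' Declares inputs (a synthetic benchmark config, or file paths for edge
#' table / gene table / expression / gene sets), the stage thresholds, and
#' the global seed from which per-stage seeds are derived by fixed
#' offsets so stages can be rerun in isolation.
#'
#' @param synthetic A [synthetic_config()] (used when no paths given).
#' @param edge_path,gene_table_path,expression_path,gene_sets_path
#'   Optional file inputs; when `edge_path` is set the pipeline runs on
#'   files instead of the synthetic generator.
#' @param confidence_threshold Edge-confidence cutoff (default 0.7).
#' @param hub_percentile Hub percentile (default 80).
#' @param coexpression_r Co-expression cutoff (default 0.7).
#' @param mldpp [mldpp_config()].
#' @param train [train_config()].
#' @param m_pos,m_neg Contrastive margins.
#' @param k Number of embedding clusters.
#' @param weights Priority weights (hub, mldpp, druggability).
#' @param n_samples Expression samples (synthetic runs).
#' @param train_epochs Epoch budget override for the embedding stage.
#' @param seed Global seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            edge_path = NULL, gene_table_path = NULL,
                            expression_path = NULL, gene_sets_path = NULL,
                            confidence_threshold = 0.7, hub_percentile = 80,
                            coexpression_r = 0.7,
                            mldpp = mldpp_config(),
                            train = train_config(),
                            m_pos = 0.5, m_neg = 1.5,
                            k = 5, weights = c(0.2, 0.3, 0.5),
                            n_samples = 50, train_epochs = NULL,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_bad("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Network construction -> topology and hub classification -> dynamic
#' perturbation propagation -> hypergraph assembly -> embedding training
#' and clustering -> enrichment -> prioritization, on synthetic or file
#' inputs. Identical config and seed give an identical bundle. A stage
#' failure halts the pipeline with the failing stage named.
#'
#' @param config A [pipeline_config()].
#' @return Named list bundle with every stage artifact and a one-row
#'   `summary` tibble.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  if (is.null(config$edge_path)) {
    syn <- config$synthetic
    syn$seed <- seed
    bench <- run_stage("synthetic_data", simulate_benchmark(syn, config$n_samples))
    network <- bench$network
    gene_table <- bench$gene_table
    expression <- bench$expression
    gene_sets <- bench$pathway_sets
    truth <- bench$truth
  } else {
    network <- run_stage("network_io",
                         read_edge_table(config$edge_path,
                                         config$confidence_threshold))
    gene_table <- if (!is.null(config$gene_table_path)) {
      run_stage("network_io", read_gene_table(config$gene_table_path))
    } else NULL
    expression <- if (!is.null(config$expression_path)) {
      run_stage("network_io", read_expression(config$expression_path))
    } else NULL
    gene_sets <- if (!is.null(config$gene_sets_path)) {
      run_stage("network_io", read_gene_sets(config$gene_sets_path))
    } else NULL
    truth <- NULL
  }

  topo <- run_stage("topology", {
    cent <- centrality_profile(network)
    scores <- perturbation_scores(network)
    hubs <- classify_hubs(scores, config$hub_percentile)
    pl <- fit_power_law(cent$degree)
    gc <- giant_component(network)
    list(centralities = cent, scores = scores, hubs = hubs,
         power_law = pl, components = gc$report)
  })

  mld <- run_stage("mldpp", {
    if (is.null(gene_table)) stop("gene annotations required for stratified seeding")
    p0 <- initialize_perturbation(gene_table, topo$hubs, network)
    run <- run_mldpp(network, p0, config$mldpp)
    metrics <- mldpp_metrics(run, topo$scores)
    list(run = run, metrics = metrics, p0 = p0)
  })

  hyper <- run_stage("hypergraph", {
    sources <- list(clique = clique_hyperedges(network))
    if (!is.null(expression)) {
      sources$coexpression <- coexpression_hyperedges(expression,
                                                      config$coexpression_r)
    } else {
      message("no expression input: co-expression hyperedges skipped")
    }
    if (!is.null(gene_sets)) {
      sources$reactome_pathway <- pathway_hyperedges(gene_sets,
                                                     igraph::V(network)$name)
    }
    hg <- assemble_hypergraph(sources, igraph::V(network)$name)
    cohesion <- module_cohesion(hg, mld$metrics, topo$hubs, network)
    list(hg = hg, cohesion = cohesion,
         summary = hypergraph_summary(hg, network))
  })

  embed <- run_stage("hgnn_embed", {
    fm <- build_feature_matrix(topo$centralities, mld$metrics, gene_table,
                               topo$scores, "topology7")
    tc <- config$train
    tc$seed <- seed + 10L
    if (!is.null(config$train_epochs)) tc$max_epochs <- config$train_epochs
    hub_vec <- topo$hubs$is_hub[match(hyper$hg$nodes, topo$hubs$gene)]
    fit <- train_hgnn(hyper$hg, fm$X[hyper$hg$nodes, , drop = FALSE],
                      hub_vec, tc, config$m_pos, config$m_neg)
    clusters <- kmeans_clusters(fit$embedding, k = config$k,
                                seed = seed + 11L)
    quality <- cluster_quality(fit$embedding, clusters)
    pca <- project_2d(fit$embedding, "pca")
    list(features = fm, fit = fit, clusters = clusters, quality = quality,
         pca = pca)
  })

  enrich <- run_stage("stats_enrich", {
    if (is.null(gene_sets)) return(NULL)
    hub_genes <- topo$hubs$gene[topo$hubs$is_hub]
    hypergeom_enrichment(hub_genes, gene_sets, igraph::V(network)$name)
  })

  prio <- run_stage("prioritize", {
    priority_scores(topo$hubs, mld$metrics, gene_table, config$weights)
  })

  summary <- tibble::tibble(
    n_genes = igraph::vcount(network),
    n_edges = igraph::ecount(network),
    mean_degree = 2 * igraph::ecount(network) / igraph::vcount(network),
    power_law_alpha = topo$power_law$alpha,
    giant_fraction = topo$components$fraction[1],
    n_hubs = sum(topo$hubs$is_hub),
    hub_threshold = attr(topo$hubs, "threshold_value"),
    mldpp_converged_at = mld$run$converged_at,
    mean_mldpp_hub = mean(mld$metrics$final[topo$hubs$is_hub]),
    mean_mldpp_nonhub = mean(mld$metrics$final[!topo$hubs$is_hub]),
    n_hyperedges = hyper$summary$n_hyperedges,
    multiway_relationships = hyper$summary$multiway_relationships,
    multiway_gain_pct = hyper$summary$multiway_gain_pct,
    best_epoch = embed$fit$best_epoch,
    silhouette = embed$quality$silhouette,
    n_sig_sets = if (is.null(enrich)) NA_integer_ else sum(enrich$q < 0.05),
    top_target = prio$gene[1],
    seed = seed
  )

  list(network = network, gene_table = gene_table, truth = truth,
       topology = topo, mldpp = mld, hypergraph = hyper,
       embedding = embed, enrichment = enrich, priorities = prio,
       summary = summary, config = config)
}
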