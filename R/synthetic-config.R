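#' Configuration for the synthetic SFARI/STRING-like data generator
#'
#' Bundles every tunable of the synthetic benchmark: network size and
#' degree-tail shape, edge-confidence range, evidence-category mix, planted
#' co-expression module layout, pathway-set layout, and expression noise.
#' The defaults emulate the study conditions of a curated autism risk-gene
#' panel on a high-confidence STRING subnetwork: roughly 900 genes, mean
#' degree about 8, degree-tail exponent 1.52, and edge confidences in
#' (0.7, 1].
#'
#' @param n_genes Number of genes (network nodes).
#' @param target_exponent Power-law exponent the continuous MLE should
#'   recover from the generated degree sequence (see [fit_power_law()]).
#' @param mean_degree Expected edges per node.
#' @param conf_range Length-2 numeric, exclusive-lower / inclusive-upper
#'   bounds for edge confidences; must satisfy `0 < low < high <= 1`.
#' @param frac_category Named proportions over evidence categories
#'   `c("1","2","3","S","unknown")`, summing to 1. Two presets are shipped,
#'   see [category_preset()].
#' @param frac_high_risk Optional override for the total proportion of
#'   high-risk genes (categories 1 and 2 combined); rescales
#'   `frac_category` accordingly.
#' @param frac_hub Proportion of genes planted as high-degree cores (default 0.2, the hub prevalence implied by the 80th-percentile rule).
#' @param hub_effect_sd Additive shift (in SDs of the base distribution)
#'   applied to constraint and brain expression of planted hub genes, so
#'   hub-independent features carry signal.
#' @param n_modules,module_size_range Planted co-expression module count and
#'   size range (minimum size 3).
#' @param n_pathways,pathway_size_range Planted pathway-set count and size
#'   range (sizes must lie in \[3, 30\]).
#' @param hub_enriched_frac Fraction of pathway sets sampled with
#'   hub-enrichment (positive controls for the enrichment module).
#' @param hub_odds Sampling-odds multiplier for hub genes inside enriched
#'   pathway sets.
#' @param noise_sd Expression noise SD around the shared module factor. The
#'   default 0.45 gives a population within-module correlation of
#'   1/(1+0.45^2) = 0.83, so sample correlations exceed 0.7 with
#'   probability >= 0.95 at 50 samples.
#' @param drug_missing_frac Fraction of genes with missing druggability.
#' @param seed Integer seed; every generator is a pure function of the
#'   config including this seed.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [simulate_ppi_network()], [simulate_gene_table()],
#'   [simulate_expression()], [simulate_pathway_sets()]
#' @export
synthetic_config <- function(n_genes = 900,
                             target_exponent = 1.52,
                             mean_degree = 8,
                             conf_range = c(0.7, 1),
                             frac_category = category_preset("figure9"),
                             frac_high_risk = NULL,
                             frac_hub = 0.2,
                             hub_effect_sd = 1.5,
                             n_modules = 8,
                             module_size_range = c(3, 12),
                             n_pathways = 30,
                             pathway_size_range = c(3, 30),
                             hub_enriched_frac = 0.5,
                             hub_odds = 5,
                             noise_sd = 0.45,
                             drug_missing_frac = 0.05,
                             seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes <= 0) {
    stop_bad("n_genes must be a positive integer")
  }
  n_genes <- as.integer(n_genes)
  if (mean_degree >= n_genes - 1) {
    stop_bad("mean_degree >= n_genes - 1 is degenerate (complete graph)")
  }
  if (length(conf_range) != 2 || conf_range[1] <= 0 ||
      conf_range[1] >= conf_range[2] || conf_range[2] > 1) {
    stop_bad("conf_range must satisfy 0 < low < high <= 1")
  }
  frac_category <- normalize_categories(frac_category, frac_high_risk)
  if (module_size_range[1] < 3) stop_bad("module sizes must be >= 3")
  if (pathway_size_range[1] < 3 || pathway_size_range[2] > 30) {
    stop_bad("pathway set sizes must lie within [3, 30]")
  }
  if (noise_sd < 0) stop_bad("noise_sd must be nonnegative")
  if (frac_hub <= 0 || frac_hub >= 1) stop_bad("frac_hub must be in (0,1)")
  structure(
    list(
      n_genes = n_genes, target_exponent = target_exponent,
      mean_degree = mean_degree, conf_range = conf_range,
      frac_category = frac_category, frac_hub = frac_hub,
      hub_effect_sd = hub_effect_sd,
      n_modules = as.integer(n_modules),
      module_size_range = as.integer(module_size_range),
      n_pathways = as.integer(n_pathways),
      pathway_size_range = as.integer(pathway_size_range),
      hub_enriched_frac = hub_enriched_frac, hub_odds = hub_odds,
      noise_sd = noise_sd, drug_missing_frac = drug_missing_frac,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Evidence-category proportion presets
#'
#' Two published breakdowns of a 893-gene risk panel are in circulation and
#' disagree; both are shipped and neither is privileged. `"figure9"`
#' (default) corresponds to risk-level counts 139/478/201/75 (high, medium,
#' low, unknown), `"section24"` to 139/247/312 with the remainder unknown.
#' High risk (categories 1 and 2, split evenly here) maps to "high"; the
#' package convention maps category 3 to "medium" and S to "low".
#'
#' @param name `"figure9"` or `"section24"`.
#' @return Named proportions over `c("1","2","3","S","unknown")`.
#' @export
category_preset <- function(name = c("figure9", "section24")) {
  name <- match.arg(name)
  counts <- switch(name,
    figure9   = c(`1` = 69.5, `2` = 69.5, `3` = 478, S = 201, unknown = 75),
    section24 = c(`1` = 69.5, `2` = 69.5, `3` = 247, S = 312, unknown = 195)
  )
  counts / sum(counts)
}

normalize_categories <- function(frac_category, frac_high_risk = NULL) {
  allowed <- c("1", "2", "3", "S", "unknown")
  if (is.null(names(frac_category)) || !all(names(frac_category) %in% allowed)) {
    stop_bad("frac_category must be named with categories among {1,2,3,S,unknown}")
  }
  full <- stats::setNames(numeric(length(allowed)), allowed)
  full[names(frac_category)] <- frac_category
  if (any(full < 0) || any(full > 1)) stop_bad("category proportions must lie in [0,1]")
  if (abs(sum(full) - 1) > 1e-9) stop_bad("category proportions must sum to 1 (within 1e-9)")
  if (!is.null(frac_high_risk)) {
    if (frac_high_risk < 0 || frac_high_risk > 1) {
      stop_bad("frac_high_risk must lie in [0,1]")
    }
    hi <- c("1", "2")
    hi_sum <- sum(full[hi]); lo_sum <- sum(full) - hi_sum
    full[hi] <- if (hi_sum > 0) full[hi] * frac_high_risk / hi_sum
                else frac_high_risk / 2
    lo <- setdiff(allowed, hi)
    full[lo] <- if (lo_sum > 0) full[lo] * (1 - frac_high_risk) / lo_sum
                else (1 - frac_high_risk) / 3
  }
  full
}

# map evidence category -> risk level (package convention, see vignette)
category_to_risk <- function(category) {
  dplyr::case_match(as.character(category),
    c("1", "2") ~ "high",
    "3" ~ "medium",
    "S" ~ "low",
    .default = "unknown"
  )
}
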