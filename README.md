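# netperturb

Integrative network analysis of disease risk-gene panels on
confidence-weighted protein–protein interaction (PPI) networks, built for
the kind of question asked of curated autism risk-gene panels: which genes
occupy critical network positions, how do perturbations propagate through
the interactome, which multi-gene modules are functionally cohesive, and
which genes combine network importance with pharmacological tractability?

The package implements, end to end:

* **Composite hub scoring** — per-gene score
  `s_i = degree_centrality_i × mean(incident edge confidence)`, with hubs
  defined as genes strictly above the 80th percentile of the score
  distribution (linear-interpolation order-statistic convention; 179 hubs
  from 893 distinct scores).
* **MLDPP** (machine-learning dynamic perturbation propagation) — the
  damped, tanh-saturated diffusion
  `p(t+1) = tanh(α·A_sym·p(t) + (1−α)·p(0))` on the symmetric
  degree-normalised confidence-weighted adjacency, with stratified
  initialisation by hub status and evidence category, three conjunctive
  convergence criteria, derived per-gene metrics (final state, dynamic
  stability, propagation gain, integrated risk), comparator propagators
  (random walk with restart, heat kernel, linear damped propagation),
  Steiger's Z for dependent correlations, and a damping-sensitivity sweep.
* **Multi-evidence hypergraphs** — maximal-clique, co-expression, and
  pathway hyperedges unioned with deduplication; normalised hypergraph
  Laplacian `L = I − Dv^-1/2 H W De^-1 Hᵀ Dv^-1/2`; spectral communities;
  Newman–Girvan modularity of the clique expansion; multiplicative module
  cohesion (normalised mean perturbation × hub fraction × internal PPI
  density).
* **Hypergraph-convolution embeddings** — a three-layer network
  (7→64→32→16) trained full-batch with Adam on a squared-hinge contrastive
  margin loss separating hubs from non-hubs, with batch norm, dropout,
  early stopping, k-means clustering of embeddings, cluster-quality
  indices, PCA/t-SNE projection, and hub-independent validation
  clustering compared by Jaccard/ARI/permutation/Fisher statistics.
* **Enrichment and prioritisation** — exact hypergeometric gene-set
  enrichment with BH-FDR, Fisher's exact test, Jaccard overlap networks,
  rank-test toolbox, and druggability-weighted target priority
  (0.2·hub + 0.3·MLDPP + 0.5·druggability).
* **A synthetic benchmark generator** — scale-free weighted networks whose
  fitted degree exponent is calibrated to the requested value, stratified
  gene annotations with planted hub signal, planted co-expression modules,
  and hub-enriched pathway sets, so the entire pipeline is testable with
  known ground truth and no downloads.

Everything is tibble-first: analysis functions return tibbles, fitted
objects have `tidy()`/`glance()` methods, and result types have
`autoplot()` methods.

## Worked example

```r
library(netperturb)
library(dplyr)

cfg   <- synthetic_config(n_genes = 300, seed = 42)
bench <- simulate_benchmark(cfg, n_samples = 40)

scores <- perturbation_scores(bench$network)
hubs   <- classify_hubs(scores)
glance(hubs)
#> # A tibble: 1 × 5
#>   n_genes n_hubs hub_fraction threshold_value percentile
#> 1     300     60          0.2          0.0322         80

fit_power_law(centrality_profile(bench$network)$degree)
#> power-law fit: alpha = 1.533 (xmin = 1, tail n = 300)

p0  <- initialize_perturbation(bench$gene_table, hubs, bench$network)
run <- run_mldpp(bench$network, p0)
run
#> MLDPP run: 300 genes, 40 iterations, converged at iteration 40

mldpp_metrics(run, scores) |>
  mutate(is_hub = hubs$is_hub[match(gene, hubs$gene)]) |>
  group_by(is_hub) |>
  summarise(mean_final = mean(final), mean_gain = mean(gain))
#> # A tibble: 2 × 3
#>   is_hub mean_final mean_gain
#> 1 FALSE       0.281     0.265
#> 2 TRUE        0.494     0.444

hypergeom_enrichment(hubs$gene[hubs$is_hub], bench$pathway_sets,
                     hubs$gene) |>
  arrange(q) |> head(3)
#> # A tibble: 3 × 7
#>   set   set_size observed expected ratio        p       q
#> 1 PW022       21       12      4.2  2.86 0.000102 0.00305
#> 2 PW023       10        7      2    3.5  0.000683 0.0103
#> 3 PW011       16        9      3.2  2.81 0.00105  0.0105
```

The hub classification takes the top 20% of the composite score (here 60
of 300 genes, threshold 0.032). The fitted degree exponent (1.53) recovers
the generator's target of 1.52. After propagation, hub genes hold a mean
final perturbation state of 0.49 versus 0.28 for non-hubs — network
position translates into sustained dynamic elevation, not just static
connectivity. The enrichment table flags the planted hub-enriched pathway
sets (observed counts ~3× expectation, BH q < 0.05).

The single-call pipeline runs every stage and returns a bundle with a
one-row summary:

```r
bundle <- run_pipeline(pipeline_config(seed = 1))
bundle$summary
```

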