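#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot MLDPP trajectories
#'
#' One line per gene (optionally a subset) across propagation iterations.
#'
#' @param object An `mldpp_run`.
#' @param genes Optional character vector of genes to display (default:
#'   the 20 genes with the highest final state).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.mldpp_run <- function(object, genes = NULL, ...) {
  states <- object$states
  if (is.null(genes)) {
    genes <- colnames(states)[order(-states[nrow(states), ])][
      seq_len(min(20, ncol(states)))]
  }
  df <- tibble::as_tibble(states[, genes, drop = FALSE])
  df$iteration <- seq_len(nrow(states)) - 1
  long <- tidyr::pivot_longer(df, -"iteration",
                              names_to = "gene", values_to = "state")
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$state,
                                     group = .data$gene, colour = .data$gene)) +
    ggplot2::geom_line(alpha = 0.8, show.legend = length(genes) <= 12) +
    ggplot2::labs(x = "iteration", y = "perturbation state",
                  title = "Dynamic perturbation trajectories") +
    ggplot2::theme_minimal()
}

#' Plot the perturbation-score distribution with the hub threshold
#'
#' @param object A `hub_classification`.
#' @param bins Histogram bins.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.hub_classification <- function(object, bins = 40, ...) {
  thr <- attr(object, "threshold_value")
  ggplot2::ggplot(object, ggplot2::aes(.data$score, fill = .data$is_hub)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.85, position = "identity") +
    ggplot2::geom_vline(xintercept = thr, linetype = 2) +
    ggplot2::labs(x = "perturbation score", y = "genes", fill = "hub",
                  title = sprintf("Hub threshold %.4g (%d hubs)",
                                  thr, sum(object$is_hub))) +
    ggplot2::theme_minimal()
}

#' Plot enrichment ratios
#'
#' Horizontal bars of enrichment ratio, shaded by BH q-value significance.
#'
#' @param object An `enrichment_result`.
#' @param q_cut Significance cutoff for the fill (default 0.05).
#' @param max_sets Show at most this many sets (by q).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.enrichment_result <- function(object, q_cut = 0.05, max_sets = 20, ...) {
  df <- dplyr::slice_min(tibble::as_tibble(object), .data$q, n = max_sets,
                         with_ties = FALSE)
  df$set <- stats::reorder(df$set, df$ratio)
  ggplot2::ggplot(df, ggplot2::aes(.data$ratio, .data$set,
                                   fill = .data$q < q_cut)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::labs(x = "enrichment ratio (observed / expected)", y = NULL,
                  fill = sprintf("q < %.2g", q_cut)) +
    ggplot2::theme_minimal()
}

#' Plot embedding training history
#'
#' Train / validation loss and the hub vs non-hub inter-group distance per
#' epoch.
#'
#' @param object An `hgnn_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.hgnn_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history,
                              c("train_loss", "val_loss",
                                "intergroup_distance"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Contrastive training history") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a 2-D projection coloured by cluster
#'
#' @param projection Tibble from [project_2d()].
#' @param clusters Optional tibble from [kmeans_clusters()].
#' @param hubs Optional `hub_classification` (hub genes drawn as
#'   triangles).
#' @return A ggplot.
#' @export
plot_embedding <- function(projection, clusters = NULL, hubs = NULL) {
  df <- projection
  if (!is.null(clusters)) {
    df$cluster <- factor(clusters$cluster[match(df$gene, clusters$gene)])
  }
  if (!is.null(hubs)) {
    df$hub <- hubs$is_hub[match(df$gene, hubs$gene)]
  }
  aes <- ggplot2::aes(.data$dim1, .data$dim2)
  p <- ggplot2::ggplot(df, aes)
  p <- if (!is.null(clusters) && !is.null(hubs)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster,
                                         shape = .data$hub), alpha = 0.8)
  } else if (!is.null(clusters)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster), alpha = 0.8)
  } else {
    p + ggplot2::geom_point(alpha = 0.8)
  }
  p + ggplot2::labs(x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
}
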