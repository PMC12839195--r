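#' Druggability-weighted target priority scores
#'
#' Linear combination `priority = w_hub * hub + w_mldpp * mldpp_final +
#' w_drug * druggability` with weights summing to 1 (default 0.2 / 0.3 /
#' 0.5). Genes without a druggability assessment are excluded from the
#' ranking (not silently scored 0) and counted in the `n_excluded`
#' attribute. Ties are broken by MLDPP score, then symbol.
#'
#' @param hubs [classify_hubs()] result.
#' @param mldpp_metrics [mldpp_metrics()] tibble.
#' @param gene_table Gene annotations (needs `druggability`).
#' @param weights Length-3 numeric `(hub, mldpp, druggability)`, summing
#'   to 1 within 1e-9.
#' @return Tibble of class `priority_table`: `gene`, `hub_indicator`,
#'   `mldpp_final`, `druggability`, `priority`, `rank`.
#' @export
priority_scores <- function(hubs, mldpp_metrics, gene_table,
                            weights = c(0.2, 0.3, 0.5)) {
  if (length(weights) != 3 || any(weights < 0)) {
    stop_bad("weights must be 3 nonnegative numbers")
  }
  if (abs(sum(weights) - 1) > 1e-9) stop_bad("weights must sum to 1")
  df <- tibble::tibble(
    gene = hubs$gene,
    hub_indicator = as.numeric(hubs$is_hub),
    mldpp_final = mldpp_metrics$final[match(hubs$gene, mldpp_metrics$gene)],
    druggability = gene_table$druggability[match(hubs$gene, gene_table$symbol)]
  )
  n_excluded <- sum(is.na(df$druggability))
  if (n_excluded) {
    message(n_excluded, " gene(s) without druggability excluded from ranking")
  }
  df <- dplyr::filter(df, !is.na(.data$druggability))
  df <- dplyr::mutate(df, priority = weights[1] * .data$hub_indicator +
                        weights[2] * .data$mldpp_final +
                        weights[3] * .data$druggability)
  df <- dplyr::arrange(df, dplyr::desc(.data$priority),
                       dplyr::desc(.data$mldpp_final), .data$gene)
  df <- dplyr::mutate(df, rank = dplyr::row_number())
  attr(df, "n_excluded") <- n_excluded
  attr(df, "weights") <- weights
  class(df) <- c("priority_table", class(df))
  df
}

#' Rank therapeutic targets and compare top-n against the rest
#'
#' Returns the top `top_n` rows of the priority table plus a two-sample
#' rank test (Mann--Whitney with rank-biserial effect size) comparing
#' priority scores of the top set against all remaining ranked genes.
#'
#' @param table [priority_scores()] result.
#' @param top_n Number of top targets (below the table size).
#' @return List: `top` (tibble), `test` (list `U`, `p`, `effect_r`).
#' @export
rank_targets <- function(table, top_n = 10) {
  if (top_n >= nrow(table)) stop_bad("top_n must be below the table size")
  ord <- dplyr::arrange(table, .data$rank)
  top <- ord[seq_len(top_n), ]
  rest <- ord[-seq_len(top_n), ]
  test <- mann_whitney(top$priority, rest$priority)
  list(top = top, test = test)
}
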