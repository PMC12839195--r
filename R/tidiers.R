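#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a power-law fit
#'
#' @param x A `power_law_fit`.
#' @param ... Ignored.
#' @return One-row tibble: `alpha`, `xmin`, `r_squared`, `gof_p`,
#'   `n_tail`.
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, xmin = x$xmin, r_squared = x$r_squared,
                 gof_p = x$gof_p, n_tail = x$n_tail)
}

#' @rdname tidy.power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) tidy.power_law_fit(x)

#' Tidy an MLDPP run into a long iteration-by-gene tibble
#'
#' @param x An `mldpp_run`.
#' @param ... Ignored.
#' @return Tibble: `iteration`, `gene`, `state`.
#' @export
tidy.mldpp_run <- function(x, ...) {
  df <- tibble::as_tibble(x$states)
  df$iteration <- seq_len(nrow(x$states)) - 1
  tidyr::pivot_longer(df, -"iteration", names_to = "gene",
                      values_to = "state")
}

#' One-row summary of an MLDPP run
#'
#' @param x An `mldpp_run`.
#' @param ... Ignored.
#' @return Tibble: `n_genes`, `iterations`, `converged`, `converged_at`,
#'   `alpha`.
#' @export
glance.mldpp_run <- function(x, ...) {
  tibble::tibble(n_genes = ncol(x$states),
                 iterations = nrow(x$states) - 1,
                 converged = !is.na(x$converged_at),
                 converged_at = x$converged_at,
                 alpha = x$config$alpha)
}

#' One-row summary of a hub classification
#'
#' @param x A `hub_classification`.
#' @param ... Ignored.
#' @return Tibble: `n_genes`, `n_hubs`, `hub_fraction`,
#'   `threshold_value`, `percentile`.
#' @export
glance.hub_classification <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x), n_hubs = sum(x$is_hub),
                 hub_fraction = mean(x$is_hub),
                 threshold_value = attr(x, "threshold_value"),
                 percentile = attr(x, "percentile"))
}

#' One-row summary of a trained embedding network
#'
#' @param x An `hgnn_fit`.
#' @param ... Ignored.
#' @return Tibble with epoch counts, losses, and the inter-group distance
#'   change.
#' @export
glance.hgnn_fit <- function(x, ...) {
  h <- x$history
  at <- function(col, epoch) h[[col]][match(epoch, h$epoch)]
  tibble::tibble(
    epochs_run = max(h$epoch),
    best_epoch = x$best_epoch,
    initial_train_loss = at("train_loss", 1),
    best_train_loss = at("train_loss", x$best_epoch),
    best_val_loss = at("val_loss", x$best_epoch),
    initial_intergroup = at("intergroup_distance", 0),
    best_intergroup = at("intergroup_distance", x$best_epoch),
    loss_reduction_pct = 100 * (1 - at("train_loss", x$best_epoch) /
                                  at("train_loss", 1))
  )
}
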