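#' Assemble and standardize a node feature matrix
#'
#' Three variants: `"topology7"` -- degree centrality, betweenness,
#' closeness, clustering coefficient, static perturbation score, MLDPP
#' final score, dynamic stability (in that documented order);
#' `"hub_independent5"` -- evidence-category score, gene length,
#' constraint, brain expression, pathway count (no centrality column);
#' `"hub_independent3"` -- clustering coefficient, panel-membership
#' indicator, log degree. All columns are z-scored to zero mean and unit
#' variance; constant columns are kept unscaled and flagged.
#'
#' @param centralities [centrality_profile()] tibble.
#' @param mldpp_metrics [mldpp_metrics()] tibble (may be `NULL` for the
#'   hub-independent variants).
#' @param gene_table Gene annotations.
#' @param static_scores [perturbation_scores()] tibble (topology7 only).
#' @param variant Feature-set variant.
#' @return Object of class `feature_matrix`: `X` (standardized matrix,
#'   genes in rows), `center`, `scale`, `constant` (flag per column),
#'   `variant`.
#' @export
build_feature_matrix <- function(centralities, mldpp_metrics = NULL,
                                 gene_table, static_scores = NULL,
                                 variant = c("topology7", "hub_independent5",
                                             "hub_independent3")) {
  variant <- match.arg(variant)
  genes <- centralities$gene
  raw <- switch(variant,
    topology7 = {
      if (is.null(mldpp_metrics) || is.null(static_scores)) {
        stop_bad("topology7 needs mldpp_metrics and static_scores")
      }
      mi <- match(genes, mldpp_metrics$gene)
      si <- match(genes, static_scores$gene)
      cbind(
        degree_centrality = centralities$degree_centrality,
        betweenness = centralities$betweenness,
        closeness = centralities$closeness,
        clustering_coef = centralities$clustering_coef,
        perturbation_score = static_scores$score[si],
        mldpp_final = mldpp_metrics$final[mi],
        dynamic_stability = mldpp_metrics$stability[mi]
      )
    },
    hub_independent5 = {
      gi <- match(genes, gene_table$symbol)
      cat_score <- dplyr::case_match(gene_table$category[gi],
        "1" ~ 3, "2" ~ 2, "3" ~ 1, "S" ~ 2, .default = 0)
      cbind(
        category_score = cat_score,
        gene_length_kb = gene_table$gene_length_kb[gi],
        constraint = gene_table$constraint[gi],
        brain_expression = gene_table$brain_expression[gi],
        pathway_count = gene_table$pathway_count[gi]
      )
    },
    hub_independent3 = {
      gi <- match(genes, gene_table$symbol)
      cbind(
        clustering_coef = centralities$clustering_coef,
        panel_member = as.numeric(gene_table$category[gi] != "unknown"),
        log_degree = log1p(centralities$degree)
      )
    }
  )
  rownames(raw) <- genes
  if (anyNA(raw)) stop_bad("feature matrix has missing values; align inputs first")
  center <- colMeans(raw)
  scale_ <- apply(raw, 2, stats::sd)
  constant <- scale_ < 1e-12
  scale_[constant] <- 1
  X <- sweep(sweep(raw, 2, center), 2, scale_, "/")
  structure(list(X = X, center = center, scale = scale_,
                 constant = constant, variant = variant),
            class = "feature_matrix")
}

#' Initialize hypergraph-convolution network parameters
#'
#' Three layers with progressive dimensionality reduction
#' (`n_features -> 64 -> 32 -> 16` by default), each holding a Xavier-
#' initialized transform, batch-norm scale/shift and running moments.
#'
#' @param n_features Input feature count.
#' @param dims Hidden/output widths.
#' @param dropout Dropout rate during training.
#' @param seed RNG seed for the initialization.
#' @return Object of class `hgnn_params`.
#' @export
hgnn_init <- function(n_features, dims = c(64, 32, 16), dropout = 0.2,
                      seed = 1L) {
  set.seed(seed)
  sizes <- c(n_features, dims)
  layers <- purrr::map(seq_along(dims), function(l) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1]
    lim <- sqrt(6 / (fan_in + fan_out))
    # small-gain output layer: embeddings start compact so the negative
    # margin drives separation outward (metric-learning convention)
    if (l == length(dims)) lim <- lim * 0.1
    list(
      Theta = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
      bn_gamma = rep(1, fan_out), bn_beta = rep(0, fan_out),
      run_mean = rep(0, fan_out), run_var = rep(1, fan_out)
    )
  })
  structure(list(layers = layers, dims = dims, dropout = dropout,
                 bn_momentum = 0.9, bn_eps = 1e-5),
            class = "hgnn_params")
}

# forward pass; returns final embedding plus per-layer caches for backprop.
# Batch norm is applied to the hidden layers only: normalizing the final
# 16-dim layer would pin the embedding scale and fight both contrastive
# margins. `bn = "batch"` uses current batch statistics (training and
# deterministic diagnostics), `bn = "running"` the tracked moments.
hgnn_forward_cache <- function(P, X, params, dropout = FALSE,
                               bn = c("batch", "running"),
                               update_running = FALSE) {
  bn <- match.arg(bn)
  caches <- list()
  inp <- X
  n_layers <- length(params$layers)
  for (l in seq_len(n_layers)) {
    ly <- params$layers[[l]]
    A <- as.matrix(P %*% inp)
    Z <- A %*% ly$Theta
    has_bn <- l < n_layers
    if (has_bn) {
      if (bn == "batch") {
        mu <- colMeans(Z)
        v <- colMeans(sweep(Z, 2, mu)^2)
        if (update_running) {
          mom <- params$bn_momentum
          params$layers[[l]]$run_mean <- mom * ly$run_mean + (1 - mom) * mu
          params$layers[[l]]$run_var <- mom * ly$run_var + (1 - mom) * v
        }
      } else {
        mu <- ly$run_mean
        v <- ly$run_var
      }
      inv_sd <- 1 / sqrt(v + params$bn_eps)
      Zh <- sweep(sweep(Z, 2, mu), 2, inv_sd, "*")
      Y <- sweep(sweep(Zh, 2, ly$bn_gamma, "*"), 2, ly$bn_beta, "+")
      act <- pmax(Y, 0)
    } else {
      mu <- NULL; v <- NULL; inv_sd <- NULL; Zh <- NULL
      Y <- Z
      act <- Y
    }
    mask <- NULL
    out <- act
    if (dropout && params$dropout > 0 && l < n_layers) {
      mask <- matrix(stats::rbinom(length(act), 1, 1 - params$dropout),
                     nrow(act)) / (1 - params$dropout)
      out <- act * mask
    }
    caches[[l]] <- list(A = A, Z = Z, mu = mu, inv_sd = inv_sd, Zh = Zh,
                        Y = Y, mask = mask, has_bn = has_bn)
    inp <- out
  }
  list(embedding = inp, caches = caches, params = params)
}

#' Hypergraph-convolution forward pass
#'
#' Each layer propagates node features through the normalized hypergraph
#' operator `Dv^(-1/2) H W De^(-1) H^T Dv^(-1/2)`, applies the learned
#' transform, batch normalization, a rectifier nonlinearity (identity on
#' the final 16-dim layer, preserving metric structure for the
#' contrastive loss) and, in training mode, dropout. Evaluation mode is
#' deterministic and uses the running batch-norm moments.
#'
#' @param hg A `gene_hypergraph`.
#' @param X Standardized feature matrix (rows = `hg$nodes`) or a
#'   `feature_matrix`.
#' @param params [hgnn_init()] parameters.
#' @param training Training-mode flag (batch statistics + dropout).
#' @return List: `embedding` (genes x final dim), `layers` (per-layer
#'   post-activation outputs).
#' @export
hgnn_forward <- function(hg, X, params, training = FALSE) {
  stopifnot(inherits(hg, "gene_hypergraph"))
  if (inherits(X, "feature_matrix")) X <- X$X
  if (nrow(X) != length(hg$nodes)) stop_bad("feature rows must match hypergraph nodes")
  P <- hypergraph_operator(hg)
  fw <- hgnn_forward_cache(P, X, params, dropout = training,
                           bn = if (training) "batch" else "running")
  list(embedding = fw$embedding,
       layers = purrr::map(fw$caches, "Y"),
       conv = purrr::map(fw$caches, "Z"))
}

#' Contrastive margin loss
#'
#' Mean squared hinge over hub--hub pairs farther apart than the positive
#' margin plus mean squared hinge over hub--nonhub pairs closer than the
#' negative margin (Euclidean distances, full pair enumeration).
#'
#' @param embeddings Numeric matrix (genes x dims).
#' @param hub_labels Logical vector (TRUE = hub).
#' @param m_pos,m_neg Positive / negative margins (defaults 0.5 / 1.5).
#' @return Loss value (scalar).
#' @export
contrastive_loss <- function(embeddings, hub_labels, m_pos = 0.5, m_neg = 1.5) {
  contrastive_loss_grad(embeddings, hub_labels, m_pos, m_neg,
                        want_grad = FALSE)$loss
}

contrastive_loss_grad <- function(E, hub, m_pos = 0.5, m_neg = 1.5,
                                  want_grad = TRUE) {
  if (m_pos <= 0 || m_pos >= m_neg) stop_bad("margins must satisfy 0 < m_pos < m_neg")
  hub <- as.logical(hub)
  if (!any(hub) || all(hub)) stop_bad("need at least one hub and one non-hub")
  n <- nrow(E)
  sq <- rowSums(E^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(E), 0)
  D <- sqrt(D2)
  hh <- outer(hub, hub, "&"); diag(hh) <- FALSE
  # cross pairs: exactly one of the two is a hub
  cross <- outer(hub, hub, FUN = function(a, b) a != b)
  diag(cross) <- FALSE
  n_pos <- sum(hh) / 2
  n_neg <- sum(cross) / 2
  pos_viol <- pmax(D - m_pos, 0) * hh
  neg_viol <- pmax(m_neg - D, 0) * cross
  loss <- (if (n_pos > 0) sum(pos_viol^2) / 2 / n_pos else 0) +
          (if (n_neg > 0) sum(neg_viol^2) / 2 / n_neg else 0)
  if (!want_grad) return(list(loss = loss))
  # dL/dd per ordered pair; summing the ordered entries once per row
  # reproduces the unordered-pair chain rule (factor 2 from v^2)
  G <- matrix(0, n, n)
  if (n_pos > 0) G <- G + 2 * (pos_viol / n_pos)
  if (n_neg > 0) G <- G - 2 * (neg_viol / n_neg)
  Dsafe <- D; Dsafe[Dsafe == 0] <- Inf
  Gd <- G / Dsafe
  grad <- (rowSums(Gd) * E) - Gd %*% E
  list(loss = loss, grad = grad)
}

# full forward + backward: contrastive loss on the rows in `idx` and
# analytic gradients for every learnable parameter. Used by train_hgnn()
# and directly checkable against finite differences (dropout off).
hgnn_loss_grads <- function(P, X, params, hub, idx, m_pos = 0.5, m_neg = 1.5,
                            weight_decay = 0, dropout = FALSE,
                            update_running = FALSE) {
  n_layers <- length(params$layers)
  fw <- hgnn_forward_cache(P, X, params, dropout = dropout, bn = "batch",
                           update_running = update_running)
  E <- fw$embedding
  lg <- contrastive_loss_grad(E[idx, , drop = FALSE], hub[idx], m_pos, m_neg)
  dE <- matrix(0, nrow(E), ncol(E))
  dE[idx, ] <- lg$grad
  grads <- vector("list", n_layers)
  delta <- dE
  for (l in rev(seq_len(n_layers))) {
    cache <- fw$caches[[l]]
    ly <- params$layers[[l]]
    if (!is.null(cache$mask)) delta <- delta * cache$mask
    if (l < n_layers) delta <- delta * (cache$Y > 0)
    if (cache$has_bn) {
      # batch norm backward (population statistics over the full batch)
      m <- nrow(delta)
      dgamma <- colSums(delta * cache$Zh)
      dbeta <- colSums(delta)
      dZh <- sweep(delta, 2, ly$bn_gamma, "*")
      Zc <- sweep(cache$Z, 2, cache$mu)
      dvar <- colSums(dZh * Zc) * (-0.5) * cache$inv_sd^3
      dmu <- colSums(dZh) * (-cache$inv_sd) + dvar * colMeans(-2 * Zc)
      dZ <- sweep(dZh, 2, cache$inv_sd, "*") +
        sweep(Zc, 2, 2 * dvar / m, "*") +
        matrix(dmu / m, m, length(dmu), byrow = TRUE)
    } else {
      dgamma <- NULL; dbeta <- NULL
      dZ <- delta
    }
    dTheta <- crossprod(cache$A, dZ) + weight_decay * ly$Theta
    grads[[l]] <- list(Theta = dTheta, gamma = dgamma, beta = dbeta)
    if (l > 1) {
      dA <- dZ %*% t(ly$Theta)
      delta <- as.matrix(P %*% dA)   # P is symmetric
    }
  }
  list(loss = lg$loss, grads = grads, params = fw$params, embedding = E)
}

#' Training configuration for the embedding network
#'
#' Adam moments, learning-rate schedule (exponential decay every 10
#' epochs), weight decay, epoch budget, early-stopping patience, and the
#' held-out validation fraction.
#'
#' @param learning_rate,decay_factor,decay_every,weight_decay,
#'   beta1,beta2,eps Optimizer settings.
#' @param max_epochs,patience Epoch budget and early-stopping patience.
#' @param val_fraction Fraction of genes held out for validation loss.
#' @param seed RNG seed (initialization, split, dropout).
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, decay_factor = 0.95,
                         decay_every = 10, weight_decay = 1e-5,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         max_epochs = 100, patience = 15,
                         val_fraction = 0.1, seed = 1L) {
  if (patience >= max_epochs) stop_bad("patience must be below max_epochs")
  structure(as.list(environment()), class = "train_config")
}

#' Train the hypergraph-convolution embedding network
#'
#' Full-batch Adam on the contrastive margin loss. A stratified 10%
#' validation gene set is held out for early stopping; the history records
#' train loss, validation loss, and the inter-group distance (mean
#' pairwise Euclidean distance between hub and non-hub embeddings in
#' evaluation mode) per epoch. Fixed seeds give identical histories.
#'
#' @param hg A `gene_hypergraph`.
#' @param X Feature matrix or `feature_matrix` (rows = `hg$nodes`).
#' @param hub_labels Logical vector aligned with `hg$nodes`.
#' @param config [train_config()].
#' @param m_pos,m_neg Contrastive margins.
#' @param dims,dropout Network shape settings (see [hgnn_init()]).
#' @return Object of class `hgnn_fit`: `params` (best epoch), `history`
#'   (tibble), `best_epoch`, `embedding` (evaluation-mode embedding at the
#'   best parameters).
#' @export
train_hgnn <- function(hg, X, hub_labels, config = train_config(),
                       m_pos = 0.5, m_neg = 1.5,
                       dims = c(64, 32, 16), dropout = 0.2) {
  stopifnot(inherits(hg, "gene_hypergraph"))
  if (inherits(X, "feature_matrix")) X <- X$X
  hub <- as.logical(hub_labels)
  n <- nrow(X)
  if (length(hub) != n) stop_bad("hub_labels length mismatch")
  if (!any(hub) || all(hub)) stop_bad("need both hub and non-hub genes to train")
  P <- hypergraph_operator(hg)

  set.seed(config$seed)
  params <- hgnn_init(ncol(X), dims = dims, dropout = dropout,
                      seed = config$seed)
  # stratified validation split
  val <- logical(n)
  for (grp in list(which(hub), which(!hub))) {
    n_val <- max(1, round(config$val_fraction * length(grp)))
    val[sample(grp, n_val)] <- TRUE
  }
  if (!any(hub[val]) || !any(!hub[val])) {
    val[sample(which(hub), 1)] <- TRUE
    val[sample(which(!hub), 1)] <- TRUE
  }
  train_idx <- which(!val); val_idx <- which(val)

  adam <- purrr::map(params$layers, function(ly) {
    list(mTheta = ly$Theta * 0, vTheta = ly$Theta * 0,
         mg = ly$bn_gamma * 0, vg = ly$bn_gamma * 0,
         mb = ly$bn_beta * 0, vb = ly$bn_beta * 0)
  })
  n_layers <- length(params$layers)
  diagnostics <- function(pars) {
    ev <- hgnn_forward_cache(P, X, pars, dropout = FALSE, bn = "batch")$embedding
    list(val_loss = contrastive_loss(ev[val_idx, , drop = FALSE],
                                     hub[val_idx], m_pos, m_neg),
         inter = mean_intergroup_distance(ev, hub))
  }
  d0 <- diagnostics(params)
  history <- vector("list", config$max_epochs + 1)
  history[[1]] <- tibble::tibble(
    epoch = 0L, train_loss = NA_real_, val_loss = d0$val_loss,
    intergroup_distance = d0$inter, learning_rate = NA_real_
  )
  best <- list(loss = Inf, epoch = 0L, params = params)
  wait <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    lr <- config$learning_rate *
      config$decay_factor^floor((epoch - 1) / config$decay_every)

    lg <- hgnn_loss_grads(P, X, params, hub, train_idx, m_pos, m_neg,
                          weight_decay = config$weight_decay,
                          dropout = TRUE, update_running = TRUE)
    params <- lg$params
    train_loss <- lg$loss
    if (!is.finite(train_loss)) stop_bad("non-finite training loss at epoch %d", epoch)
    grads <- lg$grads
    # Adam update
    t_adam <- epoch
    for (l in seq_len(n_layers)) {
      g <- grads[[l]]; st <- adam[[l]]
      upd <- function(m, v, grad) {
        m <- config$beta1 * m + (1 - config$beta1) * grad
        v <- config$beta2 * v + (1 - config$beta2) * grad^2
        mhat <- m / (1 - config$beta1^t_adam)
        vhat <- v / (1 - config$beta2^t_adam)
        list(m = m, v = v, step = lr * mhat / (sqrt(vhat) + config$eps))
      }
      uT <- upd(st$mTheta, st$vTheta, g$Theta)
      params$layers[[l]]$Theta <- params$layers[[l]]$Theta - uT$step
      adam[[l]]$mTheta <- uT$m; adam[[l]]$vTheta <- uT$v
      if (!is.null(g$gamma)) {
        ug <- upd(st$mg, st$vg, g$gamma)
        ub <- upd(st$mb, st$vb, g$beta)
        params$layers[[l]]$bn_gamma <- params$layers[[l]]$bn_gamma - ug$step
        params$layers[[l]]$bn_beta <- params$layers[[l]]$bn_beta - ub$step
        adam[[l]]$mg <- ug$m; adam[[l]]$vg <- ug$v
        adam[[l]]$mb <- ub$m; adam[[l]]$vb <- ub$v
      }
    }

    d <- diagnostics(params)
    history[[epoch + 1]] <- tibble::tibble(
      epoch = epoch, train_loss = train_loss, val_loss = d$val_loss,
      intergroup_distance = d$inter, learning_rate = lr
    )
    if (d$val_loss < best$loss - 1e-12) {
      best <- list(loss = d$val_loss, epoch = epoch, params = params)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  history <- dplyr::bind_rows(history)
  final_embedding <- hgnn_forward_cache(P, X, best$params, dropout = FALSE,
                                        bn = "batch")$embedding
  rownames(final_embedding) <- hg$nodes
  structure(list(params = best$params, history = history,
                 best_epoch = best$epoch, embedding = final_embedding,
                 val_idx = val_idx, hub = hub),
            class = "hgnn_fit")
}

mean_intergroup_distance <- function(E, hub) {
  A <- E[hub, , drop = FALSE]; B <- E[!hub, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  mean(sqrt(pmax(d2, 0)))
}

#' @export
print.hgnn_fit <- function(x, ...) {
  h <- x$history
  at <- function(col, epoch) h[[col]][match(epoch, h$epoch)]
  cat(sprintf("HGNN fit: %d epochs run, best epoch %d (val loss %.4g)\n",
              max(h$epoch), x$best_epoch, at("val_loss", x$best_epoch)))
  cat(sprintf("  train loss %.4g -> %.4g; inter-group distance %.3g -> %.3g\n",
              at("train_loss", 1), at("train_loss", x$best_epoch),
              at("intergroup_distance", 0),
              at("intergroup_distance", x$best_epoch)))
  invisible(x)
}

#' K-means clustering of embeddings
#'
#' Multiple random initializations (`n_init`), keeping the minimum-inertia
#' solution; deterministic under the seed.
#'
#' @param embeddings Numeric matrix (genes x dims, rownames = genes).
#' @param k Number of clusters (>= 2, <= rows).
#' @param n_init Random restarts (default 100).
#' @param seed RNG seed.
#' @return Tibble: `gene`, `cluster`; inertia in the `inertia` attribute.
#' @export
kmeans_clusters <- function(embeddings, k = 5, n_init = 100, seed = 1L) {
  if (k < 2) stop_bad("k must be >= 2")
  if (k > nrow(embeddings)) stop_bad("k exceeds the number of genes")
  genes <- rownames(embeddings) %||% as.character(seq_len(nrow(embeddings)))
  if (k == nrow(embeddings)) {
    # every gene its own cluster; zero inertia by construction
    out <- tibble::tibble(gene = genes, cluster = seq_len(k))
    attr(out, "inertia") <- 0
    attr(out, "centers") <- embeddings
    return(out)
  }
  set.seed(seed)
  cl <- stats::kmeans(embeddings, centers = k, nstart = n_init, iter.max = 100)
  out <- tibble::tibble(gene = genes, cluster = unname(cl$cluster))
  attr(out, "inertia") <- cl$tot.withinss
  attr(out, "centers") <- cl$centers
  out
}

#' Clustering quality indices
#'
#' Mean silhouette width, Calinski--Harabasz index, and Davies--Bouldin
#' index, all with Euclidean distances.
#'
#' @param embeddings Numeric matrix.
#' @param assignment Cluster labels (vector or tibble from
#'   [kmeans_clusters()]).
#' @return One-row tibble: `silhouette`, `calinski_harabasz`,
#'   `davies_bouldin`.
#' @export
cluster_quality <- function(embeddings, assignment) {
  if (is.data.frame(assignment)) assignment <- assignment$cluster
  cl <- as.integer(factor(assignment))
  k <- length(unique(cl))
  n <- nrow(embeddings)
  if (k < 2) stop_bad("need at least 2 clusters")
  sq <- rowSums(embeddings^2)
  D <- sqrt(pmax(outer(sq, sq, "+") - 2 * tcrossprod(embeddings), 0))

  sil <- vapply(seq_len(n), function(i) {
    own <- cl == cl[i]
    a <- if (sum(own) > 1) sum(D[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(c2) {
      mean(D[i, cl == c2])
    }, numeric(1)))
    if (sum(own) == 1) return(0)
    (b - a) / max(a, b)
  }, numeric(1))

  centers <- t(vapply(sort(unique(cl)), function(c2) {
    colMeans(embeddings[cl == c2, , drop = FALSE])
  }, numeric(ncol(embeddings))))
  overall <- colMeans(embeddings)
  sizes <- as.numeric(table(cl))
  bss <- sum(sizes * rowSums(sweep(centers, 2, overall)^2))
  wss <- sum(vapply(seq_len(k), function(c2) {
    sum(sweep(embeddings[cl == c2, , drop = FALSE], 2, centers[c2, ])^2)
  }, numeric(1)))
  ch <- if (wss > 0) (bss / (k - 1)) / (wss / (n - k)) else Inf

  scatter <- vapply(seq_len(k), function(c2) {
    mean(sqrt(rowSums(sweep(embeddings[cl == c2, , drop = FALSE], 2,
                            centers[c2, ])^2)))
  }, numeric(1))
  db <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      d_ij <- sqrt(sum((centers[i, ] - centers[j, ])^2))
      if (d_ij == 0) Inf else (scatter[i] + scatter[j]) / d_ij
    }, numeric(1)))
  }, numeric(1)))

  tibble::tibble(silhouette = mean(sil), calinski_harabasz = ch,
                 davies_bouldin = db)
}

#' Two-dimensional projection of embeddings
#'
#' `method = "pca"`: principal components with a deterministic sign
#' convention (largest-magnitude loading positive) and per-component
#' explained-variance fractions. `method = "tsne"`: exact t-SNE
#' (perplexity 30, learning rate 200, 1000 iterations by default) for
#' visualization; no analysis result depends on its coordinates.
#'
#' @param embeddings Numeric matrix (>= 3 rows).
#' @param method `"pca"` or `"tsne"`.
#' @param perplexity,learning_rate,n_iter t-SNE parameters.
#' @param seed RNG seed (t-SNE initialization).
#' @return Tibble `gene`, `dim1`, `dim2`; for PCA the attribute
#'   `explained_variance` holds all component fractions.
#' @export
project_2d <- function(embeddings, method = c("pca", "tsne"),
                       perplexity = 30, learning_rate = 200,
                       n_iter = 1000, seed = 1L) {
  method <- match.arg(method)
  n <- nrow(embeddings)
  if (n < 3) stop_bad("need at least 3 genes")
  genes <- rownames(embeddings) %||% as.character(seq_len(n))
  if (method == "pca") {
    pc <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE)
    # deterministic signs: largest-|loading| entry positive
    for (j in seq_len(ncol(pc$rotation))) {
      i <- which.max(abs(pc$rotation[, j]))
      if (pc$rotation[i, j] < 0) {
        pc$rotation[, j] <- -pc$rotation[, j]
        pc$x[, j] <- -pc$x[, j]
      }
    }
    ev <- pc$sdev^2 / sum(pc$sdev^2)
    out <- tibble::tibble(gene = genes, dim1 = pc$x[, 1],
                          dim2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0)
    attr(out, "explained_variance") <- ev
    out
  } else {
    if (perplexity >= n / 3) stop_bad("perplexity must be below n/3")
    Y <- tsne_exact(embeddings, perplexity, learning_rate, n_iter, seed)
    tibble::tibble(gene = genes, dim1 = Y[, 1], dim2 = Y[, 2])
  }
}

# exact O(n^2) t-SNE; adequate for the <= ~1000-gene embedding panels
tsne_exact <- function(X, perplexity, eta, n_iter, seed) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(X), 0)
  # binary search per point for the bandwidth matching log(perplexity)
  target <- log(perplexity)
  Pcond <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    Pcond[i, -i] <- w / sum(w)
  }
  P <- (Pcond + t(Pcond)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  gain <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  for (iter in seq_len(n_iter)) {
    ex <- if (iter <= 100) 4 else 1     # early exaggeration
    mom <- if (iter <= 250) 0.5 else 0.8
    sqy <- rowSums(Y^2)
    num <- 1 / (1 + pmax(outer(sqy, sqy, "+") - 2 * tcrossprod(Y), 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    M <- (ex * P - Q) * num
    grad <- 4 * ((rowSums(M) * Y) - M %*% Y)
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- mom * inc - eta * gain * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Compare two clusterings with respect to a focus gene set
#'
#' Identifies, in each clustering, the cluster carrying the plurality of
#' the focus genes, and reports the Jaccard index between those two
#' member sets, a permutation p-value for it (random reassignment of the
#' second clustering's labels), the adjusted Rand index over the complete
#' assignments, and Fisher's exact test for focus-gene concentration in
#' the best-overlap cluster of the second clustering.
#'
#' @param assignment_a,assignment_b Tibbles (`gene`, `cluster`) over the
#'   same gene universe.
#' @param focus_set Character vector of focus genes (nonempty).
#' @param n_perm Label permutations (default 10000).
#' @param seed RNG seed.
#' @return One-row tibble: `jaccard`, `perm_p`, `adjusted_rand`,
#'   `fisher_or`, `fisher_lo`, `fisher_hi`, `fisher_p`.
#' @export
compare_clusterings <- function(assignment_a, assignment_b, focus_set,
                                n_perm = 10000, seed = 1L) {
  if (!length(focus_set)) stop_bad("focus set is empty")
  genes <- assignment_a$gene
  if (!setequal(genes, assignment_b$gene)) {
    stop_bad("clusterings must cover the same gene universe")
  }
  b <- assignment_b$cluster[match(genes, assignment_b$gene)]
  a <- assignment_a$cluster
  focus <- genes %in% focus_set

  focus_cluster <- function(cl) {
    tab <- table(cl[focus])
    members <- genes[cl == names(tab)[which.max(tab)]]
    members
  }
  ja <- jaccard_index(focus_cluster(a), focus_cluster(b))

  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    bp <- sample(b)
    jp <- jaccard_index(focus_cluster(a), {
      tab <- table(bp[focus]); genes[bp == names(tab)[which.max(tab)]]
    })
    if (jp >= ja) exceed <- exceed + 1L
  }
  perm_p <- (1 + exceed) / (1 + n_perm)

  ari <- adjusted_rand_index(a, b)

  best_b <- focus_cluster(b)
  in_cl <- genes %in% best_b
  ft <- fisher_exact_2x2(sum(focus & in_cl), sum(focus & !in_cl),
                         sum(!focus & in_cl), sum(!focus & !in_cl))
  tibble::tibble(jaccard = ja, perm_p = perm_p, adjusted_rand = ari,
                 fisher_or = ft$odds_ratio, fisher_lo = ft$ci95[1],
                 fisher_hi = ft$ci95[2], fisher_p = ft$p)
}

#' Adjusted Rand index between two label vectors
#'
#' @param a,b Cluster label vectors of equal length.
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (mx - expected)
}
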