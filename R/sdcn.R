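#' KNN sample graph
#'
#' Connects each sample to its `k_neighbors` nearest neighbors (Euclidean by
#' default), then symmetrizes by union, so degrees can exceed `k_neighbors`.
#' The diagonal is zero. Ties among equidistant neighbors (e.g. duplicated
#' samples) are resolved by index order with a warning.
#'
#' @param features Numeric sample-by-feature matrix.
#' @param k_neighbors Number of neighbors, `1 <= k < n`.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return A `sample_graph`: list with binary symmetric sparse `adjacency`,
#'   `k_neighbors`, `metric`.
#' @export
build_knn_graph <- function(features, k_neighbors = 10,
                            metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  features <- as.matrix(features)
  n <- nrow(features)
  if (k_neighbors < 1 || k_neighbors >= n) {
    abort("Need n_samples > k_neighbors >= 1.", class = "metastrat_config_error")
  }
  if (anyDuplicated(features) > 0) {
    warn("Duplicate samples: neighbor ties resolved by index order.")
  }
  D <- as.matrix(dist(features, method = metric))
  diag(D) <- Inf
  idx <- t(apply(D, 1, function(d) order(d)[seq_len(k_neighbors)]))
  i <- rep(seq_len(n), k_neighbors)
  j <- as.vector(idx)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(n, n), use.last.ij = FALSE)
  A@x[] <- 1  # union symmetrization: any duplicated entry collapses to 1
  A <- Matrix::drop0(A)
  structure(list(adjacency = A, k_neighbors = as.integer(k_neighbors),
                 metric = metric), class = "sample_graph")
}

#' Configuration of the structural deep clustering network
#'
#' Widths, epochs and loss weights of the autoencoder + graph-convolution
#' clustering model. Defaults are sized for cohort-scale inputs (hundreds of
#' samples by at most a few hundred pathway features).
#'
#' @param encoder_dims Hidden-layer widths of the encoder (decoder mirrors
#'   them).
#' @param embedding_dim Width of the latent embedding.
#' @param n_clusters Number of clusters k (>= 2).
#' @param pretrain_epochs Autoencoder pretraining epochs (full batch).
#' @param train_epochs Joint-training epochs.
#' @param learning_rate Adam learning rate.
#' @param loss_weights Length-3 weights for (reconstruction, cluster KL,
#'   graph-branch KL).
#' @param k_neighbors KNN-graph neighbor count when no graph is supplied.
#' @param activation `"relu"` (default) or `"linear"`.
#' @param label_head Branch producing the final hard labels: `"gcn"`
#'   (default, the graph-convolution assignment distribution) or `"ae"`
#'   (the Student-t soft assignment).
#' @param seed Integer seed; fixed seed gives identical assignments across
#'   runs.
#' @return A list of class `sdcn_config`.
#' @export
sdcn_config <- function(encoder_dims = c(64, 32), embedding_dim = 10,
                        n_clusters = 2, pretrain_epochs = 100,
                        train_epochs = 150, learning_rate = 5e-3,
                        loss_weights = c(1, 0.1, 0.01), k_neighbors = 10,
                        activation = c("relu", "linear"),
                        label_head = c("gcn", "ae"), seed = 1) {
  activation <- match.arg(activation)
  label_head <- match.arg(label_head)
  if (n_clusters < 2) {
    abort("`n_clusters` must be >= 2.", class = "metastrat_config_error")
  }
  if (any(c(encoder_dims, embedding_dim) < 1)) {
    abort("Layer widths must be positive.", class = "metastrat_config_error")
  }
  if (length(loss_weights) != 3 || any(loss_weights < 0)) {
    abort("`loss_weights` must be 3 nonnegative numbers.",
          class = "metastrat_config_error")
  }
  structure(list(
    encoder_dims = as.integer(encoder_dims),
    embedding_dim = as.integer(embedding_dim),
    n_clusters = as.integer(n_clusters),
    pretrain_epochs = as.integer(pretrain_epochs),
    train_epochs = as.integer(train_epochs),
    learning_rate = learning_rate,
    loss_weights = as.numeric(loss_weights),
    k_neighbors = as.integer(k_neighbors),
    activation = activation, label_head = label_head,
    seed = as.integer(seed)
  ), class = "sdcn_config")
}

## ---- low-level neural-net plumbing (full batch, hand-rolled backprop) ----

act_fun <- function(x, type) if (type == "relu") pmax(x, 0) else x
act_mask <- function(pre, type) if (type == "relu") (pre > 0) * 1 else 1

glorot_init <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

new_linear <- function(fan_in, fan_out) {
  list(W = glorot_init(fan_in, fan_out), b = rep(0, fan_out))
}

adam_state <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "replace", classes = "ANY")
}

# params/grads are nested lists of numeric arrays with identical shape
adam_step <- function(params, grads, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p) && !is.numeric(p)) {
      out <- Map(walk, p, g, s)
      return(list(p = lapply(out, `[[`, "p"), s = lapply(out, `[[`, "s")))
    }
    m <- b1 * s$m + (1 - b1) * g
    v <- b2 * s$v + (1 - b2) * g^2
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = list(m = m, v = v))
  }
  walk(params, grads, state)
}

ae_init <- function(d, config) {
  enc_dims <- c(d, config$encoder_dims, config$embedding_dim)
  dec_dims <- rev(enc_dims)
  list(
    enc = lapply(seq_len(length(enc_dims) - 1),
                 function(l) new_linear(enc_dims[l], enc_dims[l + 1])),
    dec = lapply(seq_len(length(dec_dims) - 1),
                 function(l) new_linear(dec_dims[l], dec_dims[l + 1]))
  )
}

# Forward pass; hidden encoder layers use the configured activation, the
# embedding and the reconstruction output are linear.
ae_forward <- function(params, X, activation) {
  L <- length(params$enc)
  H <- vector("list", L)      # activated representations (last = embedding)
  pre <- vector("list", L)
  inp <- X
  for (l in seq_len(L)) {
    p <- inp %*% params$enc[[l]]$W +
      matrix(params$enc[[l]]$b, nrow(inp), length(params$enc[[l]]$b),
             byrow = TRUE)
    pre[[l]] <- p
    H[[l]] <- if (l < L) act_fun(p, activation) else p
    inp <- H[[l]]
  }
  Ld <- length(params$dec)
  G <- vector("list", Ld)
  pre_d <- vector("list", Ld)
  for (l in seq_len(Ld)) {
    p <- inp %*% params$dec[[l]]$W +
      matrix(params$dec[[l]]$b, nrow(inp), length(params$dec[[l]]$b),
             byrow = TRUE)
    pre_d[[l]] <- p
    G[[l]] <- if (l < Ld) act_fun(p, activation) else p
    inp <- G[[l]]
  }
  list(H = H, pre = pre, G = G, pre_d = pre_d, Zae = H[[L]], Xhat = G[[Ld]])
}

# Backprop `dH_extra` (list of gradients at each encoder representation,
# possibly NULL) and reconstruction gradient through the autoencoder.
ae_backward <- function(params, X, fwd, dXhat, dH_extra, activation) {
  L <- length(params$enc)
  Ld <- length(params$dec)
  genc <- vector("list", L)
  gdec <- vector("list", Ld)
  delta <- dXhat
  for (l in rev(seq_len(Ld))) {
    if (l < Ld) delta <- delta * act_mask(fwd$pre_d[[l]], activation)
    inp <- if (l == 1) fwd$Zae else fwd$G[[l - 1]]
    gdec[[l]] <- list(W = t(inp) %*% delta, b = colSums(delta))
    delta <- delta %*% t(params$dec[[l]]$W)
  }
  # delta now carries d(loss)/d(Zae) from the reconstruction path
  for (l in rev(seq_len(L))) {
    if (!is.null(dH_extra[[l]])) delta <- delta + dH_extra[[l]]
    if (l < L) delta <- delta * act_mask(fwd$pre[[l]], activation)
    inp <- if (l == 1) X else fwd$H[[l - 1]]
    genc[[l]] <- list(W = t(inp) %*% delta, b = colSums(delta))
    delta <- delta %*% t(params$enc[[l]]$W)
  }
  list(enc = genc, dec = gdec)
}

recon_loss <- function(X, Xhat) mean((X - Xhat)^2)

#' Pretrain the autoencoder branch
#'
#' Full-batch Adam on the mean-squared reconstruction error. With
#' `embedding_dim == ncol(features)` and linear activations the identity map
#' is reachable and the loss approaches zero.
#'
#' @param features Numeric sample-by-feature matrix (finite values;
#'   standardize per feature before calling, as [train_sdcn()] does).
#' @param config [sdcn_config()].
#' @return A list of class `autoencoder`: `params`, `losses` (per epoch),
#'   `final_loss`, `activation`.
#' @export
pretrain_autoencoder <- function(features, config = sdcn_config()) {
  X <- as.matrix(features)
  if (!all(is.finite(X))) {
    abort("Features must be finite.", class = "metastrat_data_error")
  }
  with_seed(child_seed(config$seed, "pretrain"), {
    params <- ae_init(ncol(X), config)
    st <- adam_state(params)
    losses <- numeric(config$pretrain_epochs)
    scale <- 2 / length(X)
    for (ep in seq_len(config$pretrain_epochs)) {
      fwd <- ae_forward(params, X, config$activation)
      losses[ep] <- recon_loss(X, fwd$Xhat)
      if (!is.finite(losses[ep])) {
        abort(sprintf("Non-finite pretraining loss at epoch %d.", ep),
              class = "metastrat_training_error")
      }
      dXhat <- scale * (fwd$Xhat - X)
      grads <- ae_backward(params, X, fwd, dXhat,
                           vector("list", length(params$enc)),
                           config$activation)
      upd <- adam_step(params, grads, st, config$learning_rate, ep)
      params <- upd$p; st <- upd$s
    }
    structure(list(params = params, losses = losses,
                   final_loss = losses[length(losses)],
                   activation = config$activation),
              class = "autoencoder")
  })
}

## ---- graph-convolution branch ----

normalized_adjacency <- function(graph) {
  A <- graph$adjacency + Matrix::Diagonal(nrow(graph$adjacency))
  dinv <- 1 / sqrt(Matrix::rowSums(A))
  Matrix::Diagonal(x = dinv) %*% A %*% Matrix::Diagonal(x = dinv)
}

gcn_init <- function(d, config) {
  dims <- c(d, config$encoder_dims, config$embedding_dim, config$n_clusters)
  lapply(seq_len(length(dims) - 1),
         function(l) new_linear(dims[l], dims[l + 1]))
}

row_softmax <- function(Z) {
  Z <- exp(Z - apply(Z, 1, max))
  Z / rowSums(Z)
}

# Layer-wise delivery: GCN layer l + 1 consumes (1 - eps) * its own previous
# output mixed with eps * the autoencoder's l-th representation.
gcn_forward <- function(gparams, X, Ahat, H_ae, activation, eps = 0.5) {
  nl <- length(gparams)
  Zs <- vector("list", nl)
  pre <- vector("list", nl)
  Min <- vector("list", nl)   # the (already Ahat-multiplied) layer inputs
  M <- X
  for (l in seq_len(nl)) {
    AM <- as.matrix(Ahat %*% M)
    Min[[l]] <- AM
    p <- AM %*% gparams[[l]]$W +
      matrix(gparams[[l]]$b, nrow(AM), length(gparams[[l]]$b), byrow = TRUE)
    pre[[l]] <- p
    if (l < nl) {
      Zs[[l]] <- act_fun(p, activation)
      M <- (1 - eps) * Zs[[l]] + eps * H_ae[[l]]
    } else {
      Zs[[l]] <- row_softmax(p)
    }
  }
  list(Zs = Zs, pre = pre, Min = Min, dist = Zs[[nl]])
}

# dLogits: gradient at the final pre-softmax logits. Returns weight grads
# plus the gradients injected into each autoencoder representation.
gcn_backward <- function(gparams, fwd, Ahat, dLogits, activation, eps = 0.5) {
  nl <- length(gparams)
  g <- vector("list", nl)
  dH_ae <- vector("list", nl - 1)
  delta <- dLogits                      # gradient at pre[[l]]
  for (l in rev(seq_len(nl))) {
    g[[l]] <- list(W = t(fwd$Min[[l]]) %*% delta, b = colSums(delta))
    if (l == 1) break
    dM <- as.matrix(Ahat %*% (delta %*% t(gparams[[l]]$W)))
    dH_ae[[l - 1]] <- eps * dM
    delta <- (1 - eps) * dM * act_mask(fwd$pre[[l - 1]], activation)
  }
  list(g = g, dH_ae = dH_ae)
}

## ---- self-supervision targets ----

t_kernel <- function(Z, centers) {
  d2 <- outer(rowSums(Z^2), rowSums(centers^2), "+") - 2 * Z %*% t(centers)
  1 / (1 + pmax(d2, 0))
}

soft_assign <- function(Z, centers) {
  s <- t_kernel(Z, centers)
  pmax(s / rowSums(s), 1e-12)
}

target_distribution <- function(Q) {
  Pw <- Q^2 / matrix(colSums(Q), nrow(Q), ncol(Q), byrow = TRUE)
  Pw / rowSums(Pw)
}

# One full forward + backward pass of the joint model with a fixed target P.
# Factored out so gradients can be checked against finite differences.
sdcn_loss_grads <- function(params, gparams, centers, X, Ahat, P, config) {
  n <- nrow(X)
  lw <- config$loss_weights
  fwd <- ae_forward(params, X, config$activation)
  Q <- soft_assign(fwd$Zae, centers)
  gfwd <- gcn_forward(gparams, X, Ahat, fwd$H, config$activation)
  Zg <- pmax(gfwd$dist, 1e-12)

  l_rec <- recon_loss(X, fwd$Xhat)
  l_clu <- sum(P * log(P / Q)) / n
  l_gcn <- sum(P * log(P / Zg)) / n
  loss <- lw[1] * l_rec + lw[2] * l_clu + lw[3] * l_gcn

  # graph branch: d(KL)/d(logits) = (Z - P) / n
  dLogits <- lw[3] * (gfwd$dist - P) / n
  gb <- gcn_backward(gparams, gfwd, Ahat, dLogits, config$activation)

  # cluster KL through the Student-t kernel (the t-SNE/DEC gradient):
  # dL/dz_i = 2/n * sum_j S_ij (p_ij - q_ij) (z_i - mu_j)
  S <- t_kernel(fwd$Zae, centers)
  R <- S * (P - Q)                         # n x k
  dZae_kl <- lw[2] * (2 / n) * (fwd$Zae * rowSums(R) - R %*% centers)
  dC <- -lw[2] * (2 / n) * (t(R) %*% fwd$Zae - centers * colSums(R))

  dH_extra <- vector("list", length(params$enc))
  for (l in seq_along(gb$dH_ae)) {
    if (!is.null(gb$dH_ae[[l]])) dH_extra[[l]] <- gb$dH_ae[[l]]
  }
  Lenc <- length(params$enc)
  dH_extra[[Lenc]] <- (dH_extra[[Lenc]] %||% 0) + dZae_kl

  dXhat <- lw[1] * 2 * (fwd$Xhat - X) / length(X)
  gae <- ae_backward(params, X, fwd, dXhat, dH_extra, config$activation)

  list(loss = loss, parts = c(rec = l_rec, clu = l_clu, gcn = l_gcn),
       grads = list(ae = gae, gcn = gb$g, centers = dC),
       Q = Q, Zg = gfwd$dist, fwd = fwd)
}

#' Train the structural deep clustering network
#'
#' Joint training of an autoencoder and a graph-convolution branch over a
#' KNN sample graph. The graph branch receives each autoencoder layer's
#' representation mixed into its own (layer-wise delivery); soft cluster
#' assignments come from a Student-t kernel between the embedding and
#' cluster centers initialized by k-means on the pretrained embedding; both
#' branches are self-supervised toward the sharpened target distribution.
#' Hard labels are read from the graph branch by default.
#'
#' Features are standardized internally (zero mean, unit variance per
#' column); the same standardized features are used for the KNN graph and
#' for silhouette widths.
#'
#' @param features Numeric sample-by-feature matrix (rownames = sample ids).
#' @param graph Optional [build_knn_graph()] result aligned to `features`;
#'   built internally when `NULL`.
#' @param config [sdcn_config()].
#' @param autoencoder Optional pretrained [pretrain_autoencoder()] result;
#'   pretraining is run internally when `NULL`.
#' @return A `cluster_assignment`: tibble (`sample_id`, `cluster`,
#'   `silhouette`) with attributes `k`, `avg_silhouette`, `losses`,
#'   `config`, `features_std`.
#' @export
train_sdcn <- function(features, graph = NULL, config = sdcn_config(),
                       autoencoder = NULL) {
  X <- standardize_features(features)
  n <- nrow(X)
  if (is.null(rownames(X))) rownames(X) <- sprintf("S%04d", seq_len(n))
  if (is.null(graph)) {
    graph <- build_knn_graph(X, k_neighbors = min(config$k_neighbors, n - 1))
  }
  if (nrow(graph$adjacency) != n) {
    abort("Graph is not aligned to the features.",
          class = "metastrat_config_error")
  }
  Ahat <- normalized_adjacency(graph)
  if (is.null(autoencoder)) {
    autoencoder <- pretrain_autoencoder(X, config)
  }
  res <- with_seed(child_seed(config$seed, "train"), {
    fit_sdcn_once(X, Ahat, config, autoencoder$params)
  })
  if (length(unique(res$labels)) < config$n_clusters) {
    # one retry with re-initialized centers
    res <- with_seed(child_seed(config$seed, "retry"), {
      fit_sdcn_once(X, Ahat, config, autoencoder$params, jitter_centers = TRUE)
    })
    if (length(unique(res$labels)) < config$n_clusters) {
      abort(sprintf("Empty cluster at convergence (k = %d).",
                    config$n_clusters),
            class = "metastrat_training_error")
    }
  }
  sil <- silhouette_widths(X, res$labels)
  out <- tibble::tibble(sample_id = rownames(X),
                        cluster = res$labels,
                        silhouette = sil)
  attr(out, "k") <- config$n_clusters
  attr(out, "avg_silhouette") <- mean(sil)
  attr(out, "losses") <- res$losses
  attr(out, "config") <- config
  attr(out, "features_std") <- X
  class(out) <- c("cluster_assignment", class(out))
  out
}

fit_sdcn_once <- function(X, Ahat, config, ae_params,
                          jitter_centers = FALSE) {
  k <- config$n_clusters
  fwd0 <- ae_forward(ae_params, X, config$activation)
  # initial partition by k-means on the standardized input features, mapped
  # into the embedding as per-cluster means: at pathway-scale dimensionality
  # the reconstruction objective does not enforce distance preservation, so
  # k-means directly on the embedding is unreliable
  km <- kmeans(X, centers = k, nstart = 10, iter.max = 50)
  centers <- rowsum(fwd0$Zae, km$cluster) / as.vector(table(km$cluster))
  if (jitter_centers) {
    centers <- centers + matrix(rnorm(length(centers), sd = 0.1),
                                nrow(centers))
  }
  params <- ae_params
  gparams <- gcn_init(ncol(X), config)
  st <- adam_state(list(ae = params, gcn = gparams, centers = centers))
  losses <- matrix(NA_real_, config$train_epochs, 4,
                   dimnames = list(NULL, c("total", "rec", "clu", "gcn")))
  for (ep in seq_len(config$train_epochs)) {
    fwd <- ae_forward(params, X, config$activation)
    Q <- soft_assign(fwd$Zae, centers)
    P <- target_distribution(Q)
    lg <- sdcn_loss_grads(params, gparams, centers, X, Ahat, P, config)
    if (!is.finite(lg$loss)) {
      abort(sprintf("Non-finite training loss at epoch %d.", ep),
            class = "metastrat_training_error")
    }
    losses[ep, ] <- c(lg$loss, lg$parts)
    upd <- adam_step(list(ae = params, gcn = gparams, centers = centers),
                     lg$grads, st, config$learning_rate, ep)
    params <- upd$p$ae; gparams <- upd$p$gcn; centers <- upd$p$centers
    st <- upd$s
  }
  fwd <- ae_forward(params, X, config$activation)
  Q <- soft_assign(fwd$Zae, centers)
  P <- target_distribution(Q)
  lg <- sdcn_loss_grads(params, gparams, centers, X, Ahat, P, config)
  labels <- if (config$label_head == "gcn") {
    max.col(lg$Zg, ties.method = "first")
  } else {
    max.col(lg$Q, ties.method = "first")
  }
  list(labels = labels, losses = losses)
}

standardize_features <- function(features) {
  X <- as.matrix(features)
  if (!all(is.finite(X))) {
    abort("Features must be finite.", class = "metastrat_data_error")
  }
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1  # constant columns stay at zero after centering
  sweep(sweep(X, 2, mu), 2, sdv, "/")
}

silhouette_widths <- function(features, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)), dist(features))
  if (length(sil) == 1 && is.na(sil)) {
    abort("Silhouette undefined for a single cluster.",
          class = "metastrat_data_error")
  }
  sil[, "sil_width"]
}

#' Average silhouette width
#'
#' Mean over samples of `(b - a) / max(a, b)` with `a` the mean
#' within-cluster distance and `b` the smallest mean distance to another
#' cluster, Euclidean on the supplied features (pass the same standardized
#' features used for clustering).
#'
#' @param features Numeric sample-by-feature matrix.
#' @param labels Cluster labels (>= 2 occupied clusters, >= 3 samples).
#' @return Scalar in `[-1, 1]`.
#' @export
average_silhouette <- function(features, labels) {
  features <- as.matrix(features)
  if (nrow(features) < 3) {
    abort("Need at least 3 samples.", class = "metastrat_data_error")
  }
  if (length(unique(labels)) < 2) {
    abort("Silhouette undefined for a single occupied cluster.",
          class = "metastrat_data_error")
  }
  mean(silhouette_widths(features, labels))
}

#' Choose the cluster number by average silhouette
#'
#' Trains the SDCN for each k in `k_range` and returns the assignment whose
#' average silhouette width is highest. Per-k failures (e.g. a collapsed
#' cluster) are recorded and that k is skipped.
#'
#' @param features Numeric sample-by-feature matrix.
#' @param graph Optional shared [build_knn_graph()].
#' @param config [sdcn_config()] (its `n_clusters` is overridden per k).
#' @param k_range Integer vector of candidate k (min >= 2, max < n).
#' @return A list of class `sdcn_selection`: `best_k`, `assignment`,
#'   `silhouettes` (tibble k / avg_silhouette), `failures` (named character
#'   vector of error messages).
#' @export
select_n_clusters <- function(features, graph = NULL, config = sdcn_config(),
                              k_range = 2:10) {
  if (min(k_range) < 2) {
    abort("`k_range` must start at 2 or above.", class = "metastrat_config_error")
  }
  if (nrow(as.matrix(features)) <= max(k_range)) {
    abort("Need more samples than the largest k.",
          class = "metastrat_config_error")
  }
  fits <- list()
  failures <- character(0)
  for (k in k_range) {
    cfg_k <- config
    cfg_k$n_clusters <- as.integer(k)
    res <- tryCatch(train_sdcn(features, graph, cfg_k),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[as.character(k)] <- conditionMessage(res)
    } else {
      fits[[as.character(k)]] <- res
    }
  }
  if (length(fits) == 0) {
    abort("SDCN failed for every k in the range.",
          class = "metastrat_training_error")
  }
  sils <- vapply(fits, function(f) attr(f, "avg_silhouette"), numeric(1))
  best <- names(which.max(sils))
  structure(list(
    best_k = as.integer(best),
    assignment = fits[[best]],
    silhouettes = tibble::tibble(k = as.integer(names(sils)),
                                 avg_silhouette = unname(sils)),
    failures = failures
  ), class = "sdcn_selection")
}

#' @export
print.sdcn_selection <- function(x, ...) {
  cat(sprintf("<sdcn_selection> best k = %d (avg silhouette %.3f)\n",
              x$best_k,
              x$silhouettes$avg_silhouette[x$silhouettes$k == x$best_k]))
  print(x$silhouettes)
  invisible(x)
}
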