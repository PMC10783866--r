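test_that("KNN graph: hand cases, symmetrization, blob separation", {
  # 3 collinear points, k = 1: ends both pick the middle -> its degree is 2
  X <- matrix(c(0, 1, 2), 3, 1)
  g <- build_knn_graph(X, 1)
  deg <- Matrix::rowSums(g$adjacency)
  expect_equal(unname(deg[2]), 2)
  expect_equal(unname(Matrix::diag(g$adjacency)), rep(0, 3))
  expect_true(Matrix::isSymmetric(g$adjacency))

  # k = n - 1 gives the complete graph
  withr::with_seed(1, Y <- matrix(rnorm(12), 6, 2))
  gc <- build_knn_graph(Y, 5)
  expect_true(all(Matrix::rowSums(gc$adjacency) == 5))

  # two blobs 10 sd apart, k = 5: no cross-blob edge
  withr::with_seed(2, {
    B <- rbind(matrix(rnorm(20 * 3), 20, 3), matrix(rnorm(20 * 3, 10), 20, 3))
  })
  gb <- build_knn_graph(B, 5)
  A <- as.matrix(gb$adjacency)
  expect_equal(sum(A[1:20, 21:40]), 0)

  expect_error(build_knn_graph(B, 40), class = "metastrat_config_error")
  expect_warning(build_knn_graph(rbind(B, B[1, , drop = FALSE]), 3),
                 "Duplicate")
})

test_that("autoencoder pretraining: loss decreases, deterministic, identity-capable", {
  withr::with_seed(3, X <- matrix(rnorm(60 * 6), 60, 6))
  cfg <- sdcn_config(encoder_dims = 16, embedding_dim = 3,
                     pretrain_epochs = 40, seed = 5)
  ae <- pretrain_autoencoder(scale(X), cfg)
  expect_lt(ae$final_loss, ae$losses[1])
  ae2 <- pretrain_autoencoder(scale(X), cfg)
  expect_identical(ae$final_loss, ae2$final_loss)

  # with embedding as wide as the input and linear activations the identity
  # is reachable and reconstruction error collapses
  cfg_id <- sdcn_config(encoder_dims = 8, embedding_dim = 6,
                        pretrain_epochs = 400, learning_rate = 0.02,
                        activation = "linear", seed = 5)
  ae_id <- pretrain_autoencoder(scale(X), cfg_id)
  expect_lt(ae_id$final_loss, 0.01)
})

test_that("joint loss gradients match finite differences", {
  ms <- asNamespace("metastrat")
  withr::with_seed(11, {
    n <- 10; d <- 4
    X <- matrix(rnorm(n * d), n, d)
    cfg <- sdcn_config(encoder_dims = 3, embedding_dim = 2, n_clusters = 2,
                       activation = "linear", seed = 2)
    g <- build_knn_graph(X, 3)
    Ahat <- ms$normalized_adjacency(g)
    params <- ms$ae_init(d, cfg)
    gparams <- ms$gcn_init(d, cfg)
    centers <- matrix(rnorm(4), 2, 2)
  })
  fwd <- ms$ae_forward(params, X, cfg$activation)
  P <- ms$target_distribution(ms$soft_assign(fwd$Zae, centers))
  base <- ms$sdcn_loss_grads(params, gparams, centers, X, Ahat, P, cfg)
  eps <- 1e-6
  num_vs_analytic <- function(getter, setter, analytic) {
    v <- getter()
    idx <- seq_len(min(length(v), 12))
    for (i in idx) {
      v2 <- v; v2[i] <- v[i] + eps; setter(v2)
      lp <- ms$sdcn_loss_grads(params, gparams, centers, X, Ahat, P, cfg)$loss
      v2[i] <- v[i] - eps; setter(v2)
      lm <- ms$sdcn_loss_grads(params, gparams, centers, X, Ahat, P, cfg)$loss
      setter(v)
      expect_equal(analytic[i], (lp - lm) / (2 * eps), tolerance = 1e-5)
    }
  }
  num_vs_analytic(function() params$enc[[1]]$W,
                  function(v) params$enc[[1]]$W <<- v,
                  base$grads$ae$enc[[1]]$W)
  num_vs_analytic(function() params$dec[[2]]$W,
                  function(v) params$dec[[2]]$W <<- v,
                  base$grads$ae$dec[[2]]$W)
  num_vs_analytic(function() gparams[[2]]$W,
                  function(v) gparams[[2]]$W <<- v,
                  base$grads$gcn[[2]]$W)
  num_vs_analytic(function() centers,
                  function(v) centers <<- v,
                  base$grads$centers)
})

test_that("well-separated blobs are recovered exactly and deterministically", {
  withr::with_seed(13, {
    X <- rbind(matrix(rnorm(30 * 4), 30, 4), matrix(rnorm(30 * 4, 10), 30, 4))
  })
  truth <- rep(1:2, each = 30)
  cfg <- sdcn_config(n_clusters = 2, seed = 7)
  fit <- train_sdcn(X, config = cfg)
  expect_equal(ari(fit$cluster, truth), 1)
  expect_true(all(fit$silhouette >= -1 & fit$silhouette <= 1))
  fit2 <- train_sdcn(X, config = cfg)
  expect_identical(fit$cluster, fit2$cluster)

  # agreement with plain k-means on trivially separable structure
  km <- kmeans(scale(X), 2, nstart = 10)
  expect_gte(ari(fit$cluster, km$cluster), 0.95)

  expect_error(sdcn_config(n_clusters = 1), class = "metastrat_config_error")
})

test_that("silhouette: hand instance, limits, random-label null", {
  # two tight pairs on a line: 0, 1 | 10, 11
  X <- matrix(c(0, 1, 10, 11), 4, 1)
  lab <- c(1, 1, 2, 2)
  expect_equal(average_silhouette(X, lab),
               mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5)),
               tolerance = 1e-12)
  expect_error(average_silhouette(X, rep(1, 4)),
               class = "metastrat_data_error")
  expect_error(average_silhouette(X[1:2, , drop = FALSE], 1:2),
               class = "metastrat_data_error")

  withr::with_seed(17, {
    blob <- matrix(rnorm(500 * 3), 500, 3)
    rnd <- sample(1:2, 500, replace = TRUE)
  })
  expect_lt(abs(average_silhouette(blob, rnd)), 0.05)

  # label relabeling leaves the quality measure unchanged
  withr::with_seed(19, Z <- rbind(matrix(rnorm(40), 20, 2),
                                  matrix(rnorm(40, 5), 20, 2)))
  l1 <- rep(1:2, each = 20)
  expect_equal(average_silhouette(Z, l1), average_silhouette(Z, 3 - l1))
})

test_that("silhouette selection finds the planted cluster number", {
  withr::with_seed(23, {
    Y <- rbind(matrix(rnorm(25 * 3), 25, 3),
               matrix(rnorm(25 * 3, 8), 25, 3),
               matrix(rnorm(25 * 3, -8), 25, 3))
  })
  sel <- select_n_clusters(Y, config = sdcn_config(seed = 3), k_range = 2:5)
  expect_equal(sel$best_k, 3)
  expect_equal(ari(sel$assignment$cluster, rep(1:3, each = 25)), 1)
  expect_equal(nrow(sel$silhouettes) + length(sel$failures), 4)

  sel2 <- select_n_clusters(Y, config = sdcn_config(seed = 3), k_range = 2)
  expect_equal(sel2$best_k, 2)
  expect_error(select_n_clusters(Y, k_range = 1:3),
               class = "metastrat_config_error")
})

test_that("cluster assignment tidiers summarize the fit", {
  withr::with_seed(29, {
    X <- rbind(matrix(rnorm(20 * 3), 20, 3), matrix(rnorm(20 * 3, 6), 20, 3))
  })
  fit <- train_sdcn(X, config = sdcn_config(n_clusters = 2, seed = 1))
  gl <- glance(fit)
  expect_equal(gl$k, 2)
  expect_equal(gl$avg_silhouette, attr(fit, "avg_silhouette"))
  td <- tidy(fit)
  expect_named(td, c("sample_id", "cluster", "silhouette"))
  expect_equal(nrow(td), 40)
})
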