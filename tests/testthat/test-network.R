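test_that("edge filtering, symmetrization and isolated-node dropping", {
  e <- data.frame(gene1 = c("A", "B"), gene2 = c("B", "C"),
                  score = c(900, 500))
  net <- load_network(e, score_threshold = 700, quiet = TRUE)
  expect_setequal(net$genes, c("A", "B"))
  expect_equal(nrow(net$edges), 1)

  recip <- data.frame(gene1 = c("A", "B"), gene2 = c("B", "A"),
                      score = c(900, 800))
  net2 <- load_network(recip, quiet = TRUE)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$score, 900)

  loops <- data.frame(gene1 = "A", gene2 = "A", score = 950)
  expect_error(load_network(loops, quiet = TRUE), class = "metastrat_data_error")
  expect_error(
    load_network(data.frame(g1 = "A", g2 = "B", s = 400), quiet = TRUE),
    class = "metastrat_data_error"
  )
})

test_that("transition matrix is column-stochastic with hand-checked entries", {
  two <- load_network(data.frame(gene1 = "A", gene2 = "B", score = 800),
                      quiet = TRUE)
  W2 <- as.matrix(build_transition_matrix(two))
  expect_equal(W2, matrix(c(0, 1, 1, 0), 2,
                          dimnames = list(c("A", "B"), c("A", "B"))))

  tri <- load_network(data.frame(gene1 = c("A", "A", "B"),
                                 gene2 = c("B", "C", "C"),
                                 score = 900), quiet = TRUE)
  W3 <- as.matrix(build_transition_matrix(tri))
  expect_equal(unname(W3[, 1]), c(0, 0.5, 0.5))
  expect_equal(unname(Matrix::colSums(W3)), rep(1, 3))

  star <- load_network(data.frame(gene1 = "C", gene2 = c("L1", "L2", "L3"),
                                  score = c(701, 702, 703)), quiet = TRUE)
  Ws <- as.matrix(build_transition_matrix(star))
  expect_equal(unname(Ws[c("L1", "L2", "L3"), "C"]),
               c(701, 702, 703) / 2106)
  # binarized variant ignores the weights
  Wb <- as.matrix(build_transition_matrix(star, binarize_edges = TRUE))
  expect_equal(unname(Wb[c("L1", "L2", "L3"), "C"]), rep(1 / 3, 3))
})

test_that("restart walk: closed forms, fixed points and error handling", {
  W <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(as.numeric(drop(rwr(c(1, 0), W, rwr_params(r = 1)))), c(1, 0))
  p <- rwr(c(1, 0), W, rwr_params(r = 0.75, tol = 1e-12))
  expect_equal(as.numeric(drop(p)), c(0.8, 0.2), tolerance = 1e-9)

  ring <- load_network(ring_edges(8), quiet = TRUE)
  Wr <- build_transition_matrix(ring)
  u <- rep(1 / 8, 8)
  expect_equal(as.numeric(drop(rwr(u, Wr))), u, tolerance = 1e-9)

  expect_error(rwr(c(0.6, 0.3), W), class = "metastrat_config_error")
  expect_error(rwr(c(1, 0), W, rwr_params(max_iter = 1)),
               class = "metastrat_convergence_error")
})

test_that("iterative walk agrees with the direct linear solve", {
  for (s in 1:10) {
    net <- load_network(random_edges(60, 250, seed = s), quiet = TRUE)
    W <- build_transition_matrix(net)
    p0 <- rep(0, length(net$genes))
    p0[((s * 7) %% length(p0)) + 1] <- 1
    it <- rwr(p0, W, rwr_params(tol = 1e-12))
    expect_lt(max(abs(drop(it) - rwr_direct(p0, W, 0.75))), 1e-8)
  }
})

test_that("stationary mass decays with distance from the seed on a path", {
  net <- load_network(path_edges(15), quiet = TRUE)
  W <- build_transition_matrix(net)
  p0 <- c(1, rep(0, 14))
  p <- drop(rwr(p0, W, rwr_params(tol = 1e-10)))
  expect_true(all(diff(p) <= 1e-12))
})

test_that("stationary state approaches the seed as restart goes to 1", {
  net <- load_network(random_edges(30, 120, seed = 4), quiet = TRUE)
  W <- build_transition_matrix(net)
  p0 <- rep(0, length(net$genes)); p0[3] <- 1
  dev <- vapply(c(0.5, 0.7, 0.9, 0.99), function(r) {
    max(abs(drop(rwr(p0, W, rwr_params(r = r, tol = 1e-10))) - p0))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
})

test_that("profile smoothing matches per-sample propagation and conserves mass", {
  net <- load_network(random_edges(40, 160, seed = 2), quiet = TRUE)
  genes <- net$genes
  withr::with_seed(11, {
    M <- matrix(rbinom(12 * length(genes), 1, 0.08), 12,
                dimnames = list(sprintf("P%02d", 1:12), genes))
    M[rowSums(M) == 0, 1] <- 1
  })
  sm <- smooth_profile(M, net)
  expect_equal(unname(rowSums(sm)), rep(1, 12), tolerance = 1e-8)
  expect_true(all(sm >= 0))

  # batch equals independent per-sample runs
  W <- build_transition_matrix(net)
  for (s in c(1, 5, 12)) {
    p0 <- as.numeric(M[s, ] / sum(M[s, ]))
    expect_equal(unname(sm[s, ]), as.numeric(drop(rwr(p0, W))), tolerance = 1e-12)
  }

  # single mutated gene equals the unit-seed walk
  M1 <- matrix(0, 1, length(genes), dimnames = list("X", genes))
  M1[1, 7] <- 1
  e7 <- rep(0, length(genes)); e7[7] <- 1
  expect_equal(unname(smooth_profile(M1, net)[1, ]),
               as.numeric(drop(rwr(e7, W))), tolerance = 1e-12)
})

test_that("every gene mutated on a vertex-transitive graph smooths to uniform", {
  net <- load_network(ring_edges(10), quiet = TRUE)
  M <- matrix(1, 1, 10, dimnames = list("X", net$genes))
  expect_equal(unname(smooth_profile(M, net)[1, ]), rep(0.1, 10),
               tolerance = 1e-8)
})

test_that("unmapped genes and unmappable samples are handled explicitly", {
  net <- load_network(data.frame(gene1 = c("A", "B"), gene2 = c("B", "C"),
                                 score = 900), quiet = TRUE)
  M <- matrix(c(1, 1, 0, 0,
                0, 0, 0, 1), 2, 4, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("A", "B", "Z1", "Z2")))
  expect_error(suppressMessages(smooth_profile(M, net)),
               class = "metastrat_data_error")
  sm <- suppressMessages(
    suppressWarnings(smooth_profile(M, net, on_unmapped_sample = "exclude")))
  expect_equal(rownames(sm), "S1")
  expect_equal(unname(attr(sm, "unmapped_counts")), 0)
})
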