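test_that("spec constructor enforces its invariants", {
  expect_s3_class(synthetic_spec(), "synthetic_spec")
  expect_error(synthetic_spec(baseline_mutation_rate = 0),
               class = "metastrat_config_error")
  expect_error(synthetic_spec(enrichment_factor = 0.5),
               class = "metastrat_config_error")
  expect_error(synthetic_spec(n_genes = 20, pathway_size_range = c(5, 30)),
               class = "metastrat_config_error")
  expect_error(synthetic_spec(n_pathways = 5, n_informative_pathways = 6),
               class = "metastrat_config_error")
  expect_error(synthetic_spec(n_genes = 5), class = "metastrat_config_error")
})

test_that("generated network is connected, reproducible and heavy-tailed", {
  spec <- synthetic_spec(n_genes = 10, n_samples = 20, n_pathways = 2,
                         pathway_size_range = c(3, 3),
                         n_informative_pathways = 1, avg_degree = 2, seed = 1)
  net <- generate_network(spec)
  expect_equal(length(net$genes), 10)
  expect_gte(nrow(net$edges), 9)
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE)
  expect_equal(igraph::components(g)$no, 1)
  expect_true(all(net$edges$score > 700 & net$edges$score <= 1000))

  net2 <- generate_network(spec)
  expect_identical(net$edges, net2$edges)

  big <- generate_network(synthetic_spec(n_genes = 1000, seed = 2))
  deg <- table(c(big$edges$gene1, big$edges$gene2))
  expect_gt(max(deg), 3 * mean(deg))
})

test_that("generated pathways respect sizes and show network locality", {
  spec <- synthetic_spec(n_genes = 400, n_pathways = 114,
                         pathway_size_range = c(5, 60),
                         n_informative_pathways = 10, seed = 3)
  net <- generate_network(spec)
  pw <- generate_pathways(net, spec)
  expect_length(pw, 114)
  expect_true(all(lengths(pw) >= 5 & lengths(pw) <= 60))
  expect_true(all(lengths(pw) > 0))
  expect_identical(pw, generate_pathways(net, spec))

  one <- synthetic_spec(n_genes = 400, n_pathways = 1,
                        pathway_size_range = c(3, 3),
                        n_informative_pathways = 1, seed = 3)
  expect_equal(lengths(generate_pathways(net, one)), c(PW001 = 3L))

  # locality: genes in a set are closer on the graph than random same-size sets
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                     vertices = net$genes)
  meand <- function(genes) {
    d <- igraph::distances(g, v = genes, to = genes)
    mean(d[upper.tri(d)])
  }
  set_d <- mean(vapply(pw[1:15], meand, numeric(1)))
  withr::with_seed(4, {
    rand_d <- mean(vapply(1:100, function(i) {
      meand(sample(net$genes, length(pw[[(i %% 15) + 1]])))
    }, numeric(1)))
  })
  expect_lt(set_d, rand_d)
})

test_that("cohort generation: binary, seeded, no empty profiles, calibrated censoring", {
  spec <- synthetic_spec(n_genes = 300, n_samples = 250, n_pathways = 10,
                         pathway_size_range = c(8, 15),
                         n_informative_pathways = 3,
                         baseline_mutation_rate = 0.03, seed = 7)
  net <- generate_network(spec)
  pw <- generate_pathways(net, spec)
  coh <- generate_cohort(net, pw, spec)
  expect_true(all(coh$mutations %in% c(0, 1)))
  expect_true(all(rowSums(coh$mutations) >= 1))
  expect_equal(coh$clinical$sample_id, rownames(coh$mutations))
  expect_true(all(coh$clinical$os_months > 0))
  expect_true(all(coh$clinical$os_event %in% 0:1))
  expect_lt(abs(mean(coh$clinical$os_event == 0) - spec$censoring_rate), 0.08)

  coh2 <- generate_cohort(net, pw, spec)
  expect_identical(coh$mutations, coh2$mutations)
  expect_identical(coh$clinical, coh2$clinical)
})

test_that("expected mutation burden matches the binomial model", {
  spec <- synthetic_spec(n_genes = 468, n_samples = 400, n_pathways = 5,
                         pathway_size_range = c(5, 10),
                         n_informative_pathways = 1,
                         baseline_mutation_rate = 0.01,
                         enrichment_factor = 1, seed = 9)
  net <- generate_network(spec)
  pw <- generate_pathways(net, spec)
  coh <- generate_cohort(net, pw, spec)
  # n * p = 4.68 expected mutations per sample
  expect_lt(abs(median(rowSums(coh$mutations)) - 4.7), 1.5)
})

test_that("no enrichment means no subtype difference; balancing equalizes burden", {
  spec1 <- synthetic_spec(n_genes = 500, n_samples = 500, n_pathways = 10,
                          pathway_size_range = c(10, 20),
                          n_informative_pathways = 3,
                          baseline_mutation_rate = 0.03,
                          enrichment_factor = 1, seed = 11)
  net <- generate_network(spec1)
  pw <- generate_pathways(net, spec1)
  coh <- generate_cohort(net, pw, spec1)
  a <- coh$true_labels == "A"
  info_genes <- unique(unlist(pw[coh$informative_pathways]))
  cnt <- rowSums(coh$mutations[, info_genes])
  expect_gt(t.test(cnt[a], cnt[!a])$p.value, 0.01)

  spec3 <- synthetic_spec(n_genes = 500, n_samples = 500, n_pathways = 10,
                          pathway_size_range = c(10, 20),
                          n_informative_pathways = 3,
                          baseline_mutation_rate = 0.03,
                          enrichment_factor = 3, seed = 11)
  coh3 <- generate_cohort(net, pw, spec3)
  a3 <- coh3$true_labels == "A"
  tot <- rowSums(coh3$mutations)
  # informative burden differs, total burden does not
  cnt3 <- rowSums(coh3$mutations[, info_genes])
  expect_lt(t.test(cnt3[a3], cnt3[!a3])$p.value, 1e-6)
  expect_gt(t.test(tot[a3], tot[!a3])$p.value, 0.01)
})

test_that("planted informative-burden gap grows with the enrichment factor", {
  base <- synthetic_spec(n_genes = 500, n_samples = 400, n_pathways = 10,
                         pathway_size_range = c(10, 20),
                         n_informative_pathways = 3,
                         baseline_mutation_rate = 0.03, seed = 13)
  net <- generate_network(base)
  pw <- generate_pathways(net, base)
  info_genes <- unique(unlist(pw[1:3]))
  gap <- vapply(c(1, 2, 3, 4), function(ef) {
    sp <- base; sp$enrichment_factor <- ef
    coh <- generate_cohort(net, pw, sp)
    a <- coh$true_labels == "A"
    cnt <- rowSums(coh$mutations[, info_genes])
    mean(cnt[a]) - mean(cnt[!a])
  }, numeric(1))
  expect_true(all(diff(gap) > 0))
})

test_that("null survival link yields calibrated log-rank on true labels", {
  spec <- synthetic_spec(n_genes = 200, n_samples = 300, n_pathways = 5,
                         pathway_size_range = c(5, 10),
                         n_informative_pathways = 2,
                         baseline_mutation_rate = 0.03,
                         hazard_log_ratio = 0, seed = 1)
  net <- generate_network(spec)
  pw <- generate_pathways(net, spec)
  ps <- vapply(1:30, function(s) {
    sp <- spec; sp$seed <- s
    coh <- generate_cohort(net, pw, sp)
    logrank_test(coh$clinical, coh$clinical$subtype_true)$p_value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("burden balancing rejects infeasible parameters", {
  spec <- synthetic_spec(n_genes = 100, n_samples = 20, n_pathways = 4,
                         pathway_size_range = c(20, 25),
                         n_informative_pathways = 4,
                         baseline_mutation_rate = 0.02,
                         enrichment_factor = 3, seed = 1)
  net <- generate_network(spec)
  pw <- generate_pathways(net, spec)
  expect_error(generate_cohort(net, pw, spec),
               class = "metastrat_config_error")
  coh <- generate_cohort(net, pw, spec, balance_burden = FALSE)
  expect_true(all(rowSums(coh$mutations) >= 1))
})

test_that("cohort files round-trip through the standard formats", {
  spec <- synthetic_spec(n_genes = 120, n_samples = 30, n_pathways = 4,
                         pathway_size_range = c(5, 8),
                         n_informative_pathways = 2,
                         baseline_mutation_rate = 0.05, seed = 5)
  net <- generate_network(spec)
  pw <- generate_pathways(net, spec)
  coh <- generate_cohort(net, pw, spec)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, net, pw, dir)
  expect_true(all(file.exists(paths)))
  expect_identical(read_gmt(paths[["gmt"]])[["PW001"]], pw[["PW001"]])
  m <- metastrat:::read_matrix_tsv(paths[["mutations"]])
  expect_equal(unname(m), unname(coh$mutations))
  net2 <- load_network(paths[["edges"]], quiet = TRUE)
  expect_equal(nrow(net2$edges), nrow(net$edges))
})
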