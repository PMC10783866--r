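# Independent oracles and tiny fixture builders shared across test files.

# Naive running-sum single-sample enrichment score: walks the ranked list
# position by position, accumulating the in-set / out-of-set difference.
naive_es <- function(values, gene_set, alpha) {
  ord <- order(values, seq_along(values), decreasing = c(TRUE, FALSE),
               method = "radix")
  inset <- names(values)[ord] %in% gene_set
  N <- length(values)
  m <- sum(inset)
  w <- (N - seq_len(N) + 1)^alpha
  step_in <- ifelse(inset, w, 0)
  step_in <- step_in / sum(step_in[inset])
  step_out <- ifelse(inset, 0, 1 / (N - m))
  sum(cumsum(step_in) - cumsum(step_out))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# simple deterministic graphs as edge tables (scores > 700 so nothing is
# filtered at the default threshold)
ring_edges <- function(n, score = 900) {
  ids <- sprintf("N%03d", seq_len(n))
  data.frame(gene1 = ids, gene2 = ids[c(2:n, 1)], score = score)
}

path_edges <- function(n, score = 900) {
  ids <- sprintf("N%03d", seq_len(n))
  data.frame(gene1 = ids[-n], gene2 = ids[-1], score = score)
}

random_edges <- function(n, n_edges, seed) {
  ids <- sprintf("N%03d", seq_len(n))
  withr::with_seed(seed, {
    data.frame(gene1 = sample(ids, n_edges, replace = TRUE),
               gene2 = sample(ids, n_edges, replace = TRUE),
               score = runif(n_edges, 701, 1000))
  })
}

# direct linear-system solution of the restart walk stationary state
rwr_direct <- function(p0, W, r) {
  r * solve(diag(nrow(W)) - (1 - r) * as.matrix(W), p0)
}

# small synthetic cohort shared by survival-ish tests
tiny_records <- function(times, events, ids = NULL) {
  tibble::tibble(
    sample_id = ids %||% sprintf("S%02d", seq_along(times)),
    os_months = times, os_event = events
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# demo-scale but small pipeline inputs for integration tests
small_demo <- function(dir, seed = 1, n_samples = 160) {
  make_demo(dir, seed = seed, n_samples = n_samples, n_genes = 400,
            n_pathways = 12, n_informative_pathways = 6,
            pathway_size_range = c(12, 20))
}
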