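#' Build a gene interaction network from an edge table
#'
#' Filters a STRING-style weighted edge list at an interaction-score cutoff,
#' collapses duplicate and reciprocal edges (keeping the maximum score),
#' removes self-loops, and drops genes left without any retained edge. The
#' default cutoff of 700 keeps only high-confidence interactions on the
#' 0-1000 combined-score scale.
#'
#' @param edges A data frame with three columns (gene1, gene2, score), or a
#'   path to a TSV file with such columns.
#' @param score_threshold Minimum retained score; edges with
#'   `score <= score_threshold` are dropped.
#' @param quiet Suppress the node/edge count message.
#' @return A `gene_network` object: list with `genes` (sorted unique ids),
#'   `edges` (tibble `gene1`, `gene2`, `score`, canonical gene1 < gene2) and
#'   `score_threshold`.
#' @examples
#' e <- data.frame(gene1 = c("A", "B"), gene2 = c("B", "C"),
#'                 score = c(900, 500))
#' net <- load_network(e, score_threshold = 700)
#' net$genes
#' @export
load_network <- function(edges, score_threshold = 700, quiet = FALSE) {
  if (is.character(edges) && length(edges) == 1) {
    edges <- readr::read_tsv(edges, show_col_types = FALSE, progress = FALSE)
  }
  edges <- as.data.frame(edges)
  if (ncol(edges) < 3) {
    abort("Edge table must have three columns: gene1, gene2, score.",
          class = "metastrat_data_error")
  }
  edges <- edges[, 1:3]
  names(edges) <- c("gene1", "gene2", "score")
  if (!is.numeric(edges$score)) {
    bad <- which(is.na(suppressWarnings(as.numeric(edges$score))))
    abort(sprintf("Non-numeric score at edge row %d.",
                  if (length(bad)) bad[1] else 1L),
          class = "metastrat_data_error")
  }
  edges <- tibble::as_tibble(edges) |>
    dplyr::mutate(gene1 = as.character(.data$gene1),
                  gene2 = as.character(.data$gene2)) |>
    dplyr::filter(.data$score > score_threshold, .data$gene1 != .data$gene2)
  if (nrow(edges) == 0) {
    abort("No edges remain after score filtering.", class = "metastrat_data_error")
  }
  # canonicalize unordered pairs, collapse duplicates keeping the max score
  edges <- edges |>
    dplyr::mutate(a = pmin(.data$gene1, .data$gene2),
                  b = pmax(.data$gene1, .data$gene2)) |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop") |>
    dplyr::rename(gene1 = "a", gene2 = "b")
  genes <- sort(unique(c(edges$gene1, edges$gene2)))
  if (!quiet) {
    inform(sprintf("Network: %d genes, %d interactions (score > %s).",
                   length(genes), nrow(edges), format(score_threshold)))
  }
  structure(list(genes = genes, edges = edges,
                 score_threshold = score_threshold),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d genes, %d edges (score > %s)\n",
              length(x$genes), nrow(x$edges), format(x$score_threshold)))
  invisible(x)
}

#' Sparse symmetric adjacency matrix of a network
#' @noRd
network_adjacency <- function(network, binarize_edges = FALSE) {
  i <- match(network$edges$gene1, network$genes)
  j <- match(network$edges$gene2, network$genes)
  w <- if (binarize_edges) rep(1, nrow(network$edges)) else network$edges$score
  n <- length(network$genes)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n),
                            dimnames = list(network$genes, network$genes))
  A
}

#' Column-normalized random-walk operator of a network
#'
#' Builds the column-stochastic transition matrix W with
#' `W[i, j] = weight(i, j) / sum_i weight(i, j)`. Isolated genes cannot occur
#' because [load_network()] drops them, so every column has positive degree.
#'
#' @param network A `gene_network`.
#' @param binarize_edges If `TRUE`, ignore interaction scores and treat all
#'   retained edges as weight 1 before normalization.
#' @return A sparse column-stochastic `Matrix` aligned to `network$genes`.
#' @export
build_transition_matrix <- function(network, binarize_edges = FALSE) {
  if (!inherits(network, "gene_network")) {
    abort("`network` must be a gene_network.", class = "metastrat_config_error")
  }
  if (length(network$genes) == 0) {
    abort("Network is empty.", class = "metastrat_data_error")
  }
  A <- network_adjacency(network, binarize_edges)
  deg <- Matrix::colSums(A)
  if (any(deg == 0)) {
    abort("Internal error: zero-degree column in adjacency.",
          class = "metastrat_internal_error")
  }
  W <- A %*% Matrix::Diagonal(x = 1 / deg)
  dimnames(W) <- dimnames(A)
  W
}

#' Random-walk-with-restart parameters
#'
#' @param r Restart probability in (0, 1]; default 0.75.
#' @param tol Convergence threshold: iteration stops when the max-norm change
#'   between successive iterates falls below `tol`. Default 1e-6.
#' @param max_iter Iteration cap.
#' @return A list of class `rwr_params`.
#' @export
rwr_params <- function(r = 0.75, tol = 1e-6, max_iter = 1000L) {
  if (!is.numeric(r) || length(r) != 1 || r <= 0 || r > 1) {
    abort("`r` must be in (0, 1].", class = "metastrat_config_error")
  }
  if (!is.numeric(tol) || tol <= 0) {
    abort("`tol` must be positive.", class = "metastrat_config_error")
  }
  structure(list(r = r, tol = tol, max_iter = as.integer(max_iter)),
            class = "rwr_params")
}

#' Random walk with restart to the stationary distribution
#'
#' Iterates `p_{t+1} = (1 - r) * W %*% p_t + r * p0` from `p0` until the
#' max-norm change between successive iterates is below `params$tol`,
#' returning the steady-state probability vector. With restart probability
#' `r = 1` the walk never leaves its seeds and the output equals `p0`.
#'
#' @param p0 Nonnegative seed vector summing to 1 (length = `ncol(W)`). May
#'   also be a matrix with one seed vector per column, iterated jointly.
#' @param W Column-stochastic transition matrix from
#'   [build_transition_matrix()].
#' @param params [rwr_params()].
#' @return The stationary vector (or matrix, matching `p0`), with attribute
#'   `iterations`.
#' @examples
#' W <- matrix(c(0, 1, 1, 0), 2)
#' rwr(c(1, 0), W, rwr_params(r = 0.75))  # (0.8, 0.2)
#' @export
rwr <- function(p0, W, params = rwr_params()) {
  vec_in <- is.null(dim(p0))
  P0 <- if (vec_in) matrix(p0, ncol = 1) else as.matrix(p0)
  if (nrow(P0) != ncol(W)) {
    abort("Seed length must equal the transition-matrix dimension.",
          class = "metastrat_config_error")
  }
  cs <- colSums(P0)
  if (any(abs(cs - 1) > 1e-9) || any(P0 < 0)) {
    abort("Each seed vector must be nonnegative and sum to 1.",
          class = "metastrat_config_error")
  }
  r <- params$r
  P <- P0
  it <- 0L
  repeat {
    Pn <- as.matrix((1 - r) * (W %*% P)) + r * P0
    delta <- max(abs(Pn - P))
    P <- Pn
    it <- it + 1L
    if (delta < params$tol) break
    if (it >= params$max_iter) {
      abort(sprintf("RWR did not converge in %d iterations (residual %.3e).",
                    params$max_iter, delta),
            class = "metastrat_convergence_error")
    }
  }
  out <- if (vec_in) drop(P) else P
  attr(out, "iterations") <- it
  out
}

#' Smooth binary mutation profiles over an interaction network
#'
#' For each sample the seed vector places uniform mass on the sample's
#' mutated genes that map to network nodes (all other genes zero) and is
#' propagated with [rwr()]. Mutated genes absent from the network are dropped
#' and counted per sample.
#'
#' @param mutations Binary sample-by-gene matrix with row/col names, or a
#'   data frame / TSV path whose first column is `sample_id`.
#' @param network A `gene_network`.
#' @param params [rwr_params()].
#' @param on_unmapped_sample What to do with a sample none of whose mutated
#'   genes map to the network: `"error"` (default) or `"exclude"` (dropped
#'   with a warning).
#' @param binarize_edges Passed to [build_transition_matrix()].
#' @return A `smoothed_profile`: numeric matrix samples x network genes, each
#'   row a stationary distribution summing to 1. Attributes: `iterations`,
#'   `unmapped_counts` (per-sample dropped mutated genes), `params`.
#' @export
smooth_profile <- function(mutations, network, params = rwr_params(),
                           on_unmapped_sample = c("error", "exclude"),
                           binarize_edges = FALSE) {
  on_unmapped_sample <- match.arg(on_unmapped_sample)
  mutations <- as_mutation_matrix(mutations)
  if (nrow(mutations) < 1) {
    abort("Need at least one sample.", class = "metastrat_data_error")
  }
  W <- build_transition_matrix(network, binarize_edges = binarize_edges)
  genes <- network$genes
  # case-insensitive exact match between profile genes and network nodes
  idx <- match(toupper(colnames(mutations)), toupper(genes))
  mapped <- !is.na(idx)
  if (!any(mapped)) {
    abort("No mutation-profile gene maps to the network.",
          class = "metastrat_data_error")
  }
  n_unmapped_genes <- sum(!mapped)
  if (n_unmapped_genes > 0) {
    inform(sprintf("%d profile gene(s) absent from the network were dropped.",
                   n_unmapped_genes))
  }
  M <- mutations[, mapped, drop = FALSE]
  col_of <- idx[mapped]

  n <- length(genes)
  unmapped_counts <- rowSums(mutations[, !mapped, drop = FALSE])
  mapped_counts <- rowSums(M)
  empty <- mapped_counts == 0
  if (any(empty)) {
    msg <- sprintf("%d sample(s) have no network-mapped mutations.", sum(empty))
    if (on_unmapped_sample == "error") {
      abort(paste(msg, "Set on_unmapped_sample = \"exclude\" to drop them."),
            class = "metastrat_data_error")
    }
    warn(paste(msg, "They were excluded."))
    M <- M[!empty, , drop = FALSE]
    unmapped_counts <- unmapped_counts[!empty]
    mapped_counts <- mapped_counts[!empty]
  }

  P0 <- matrix(0, nrow = n, ncol = nrow(M), dimnames = list(genes, rownames(M)))
  for (s in seq_len(nrow(M))) {
    g <- col_of[M[s, ] == 1]
    P0[g, s] <- 1 / length(g)
  }
  P <- rwr(P0, W, params)
  out <- t(P)
  attr(out, "iterations") <- attr(P, "iterations")
  attr(out, "unmapped_counts") <- setNames(unmapped_counts, rownames(M))
  attr(out, "params") <- params
  class(out) <- c("smoothed_profile", class(out))
  out
}

#' Coerce mutation input to a binary matrix with dimnames
#' @noRd
as_mutation_matrix <- function(mutations) {
  if (is.character(mutations) && length(mutations) == 1) {
    mutations <- read_matrix_tsv(mutations)
  } else if (is.data.frame(mutations)) {
    if (is.character(mutations[[1]]) || is.factor(mutations[[1]])) {
      m <- as.matrix(mutations[, -1, drop = FALSE])
      rownames(m) <- as.character(mutations[[1]])
      mutations <- m
    } else {
      mutations <- as.matrix(mutations)
    }
  }
  storage.mode(mutations) <- "double"
  assert_binary_matrix(mutations)
  mutations
}
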