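#' Dense descending ranks
#'
#' Rank 1 is the largest value. Ties are resolved by `tie_rule`: `"stable"`
#' (earlier input position wins, the default used throughout the scoring
#' kernel so results are deterministic) or `"average"` (midranks).
#'
#' @param values Numeric vector.
#' @param tie_rule `"stable"` or `"average"`.
#' @return Numeric vector of ranks, same length as `values`.
#' @examples
#' rank_transform(c(5, 1, 3))  # 1 3 2
#' @export
rank_transform <- function(values, tie_rule = c("stable", "average")) {
  tie_rule <- match.arg(tie_rule)
  if (length(values) < 1) {
    abort("Need at least one value.", class = "metastrat_data_error")
  }
  if (anyNA(values)) {
    abort("NaN/NA values cannot be ranked.", class = "metastrat_data_error")
  }
  if (tie_rule == "average") {
    return(rank(-values, ties.method = "average"))
  }
  ord <- order(values, seq_along(values), decreasing = c(TRUE, FALSE),
               method = "radix")
  ranks <- integer(length(values))
  ranks[ord] <- seq_along(values)
  ranks
}

#' Single-sample enrichment score for one gene set
#'
#' The rank-based running-sum statistic: genes are sorted by decreasing
#' value; walking down the list, in-set genes add their rank weight
#' `(N - position + 1)^alpha` normalized by the set's total weight, while
#' out-of-set genes subtract `1 / (N - m)`. The score is the integral
#' (sum over positions) of the running difference, so a set concentrated at
#' the top of the ranking scores strongly positive.
#'
#' @param values Named numeric vector of one sample's gene scores (>= 2
#'   genes).
#' @param gene_set Character vector of gene ids.
#' @param alpha Rank-weight exponent (default 0.25).
#' @return The enrichment score (scalar).
#' @export
ssgsea_sample <- function(values, gene_set, alpha = 0.25) {
  if (length(values) < 2 || is.null(names(values))) {
    abort("`values` must be a named vector of at least 2 gene scores.",
          class = "metastrat_data_error")
  }
  inset <- names(values) %in% gene_set
  m <- sum(inset)
  N <- length(values)
  if (m == 0) {
    abort("Gene set does not intersect the profile.",
          class = "metastrat_data_error")
  }
  if (m == N) {
    abort("Gene set covers every profile gene; score undefined.",
          class = "metastrat_data_error")
  }
  es_from_ranks(rank_transform(values), inset, alpha)
}

#' Closed-form enrichment score from precomputed ranks
#'
#' Equivalent to accumulating the running sum position by position: the sum
#' over positions of the in-set CDF minus the out-of-set CDF collapses to a
#' weighted sum over genes of (N - position + 1).
#' @noRd
es_from_ranks <- function(ranks, inset, alpha) {
  N <- length(ranks)
  m <- sum(inset)
  pos <- ranks                     # position in the sorted list, 1 = top
  tail_len <- N - pos + 1          # number of positions a gene contributes to
  w <- tail_len^alpha              # rank weight: top gene gets N^alpha
  w_in <- w[inset]
  in_part <- sum(w_in * tail_len[inset]) / sum(w_in)
  total_tail <- N * (N + 1) / 2
  out_part <- (total_tail - sum(tail_len[inset])) / (N - m)
  in_part - out_part
}

#' Pathway-activity matrix from a smoothed profile
#'
#' Scores every sample against every gene set with [ssgsea_sample()]. Sets
#' with no gene in the profile are dropped with a warning. With
#' `normalize = TRUE` all scores are divided by the global
#' `max(scores) - min(scores)` of the matrix, the conventional
#' single-sample-enrichment normalization; the divisor is computed per
#' cohort, so call this separately per cohort (or disable and normalize
#' jointly).
#'
#' @param profile Numeric sample-by-gene matrix (e.g. a
#'   [smooth_profile()] result).
#' @param collection Named list of gene-id character vectors (see
#'   [read_gmt()]).
#' @param alpha Rank-weight exponent.
#' @param normalize Divide by the global score range.
#' @return Numeric sample-by-set matrix with attributes `alpha`,
#'   `normalized`, and `range` (the divisor when normalized).
#' @export
activity_matrix <- function(profile, collection, alpha = 0.25,
                            normalize = TRUE) {
  profile <- as.matrix(profile)
  if (nrow(profile) < 1 || ncol(profile) < 2) {
    abort("Profile must have >= 1 sample and >= 2 genes.",
          class = "metastrat_data_error")
  }
  genes <- colnames(profile)
  N <- length(genes)
  keep <- vapply(collection, function(s) {
    k <- sum(genes %in% s)
    k > 0 && k < N
  }, logical(1))
  if (!all(keep)) {
    warn(sprintf("%d gene set(s) dropped (empty or full profile overlap).",
                 sum(!keep)))
  }
  collection <- collection[keep]
  if (length(collection) == 0) {
    abort("All gene sets were dropped.", class = "metastrat_data_error")
  }
  inset_mat <- vapply(collection, function(s) genes %in% s,
                      logical(length(genes)))

  scores <- matrix(NA_real_, nrow(profile), length(collection),
                   dimnames = list(rownames(profile), names(collection)))
  for (i in seq_len(nrow(profile))) {
    ranks <- rank_transform(profile[i, ])
    for (j in seq_along(collection)) {
      scores[i, j] <- es_from_ranks(ranks, inset_mat[, j], alpha)
    }
  }
  rng <- max(scores) - min(scores)
  if (normalize) {
    if (rng == 0) {
      abort("Degenerate score matrix: zero range.", class = "metastrat_data_error")
    }
    scores <- scores / rng
  }
  attr(scores, "alpha") <- alpha
  attr(scores, "normalized") <- normalize
  attr(scores, "range") <- rng
  scores
}

#' Gene-level profile: every gene as its own singleton set
#'
#' Projects the smoothed profile onto singleton gene sets, yielding a
#' sample-by-gene matrix of enrichment scores that plays the role of an
#' expression-like profile when mRNA data are unavailable. Column order
#' matches the profile's gene order; each sample's scores are a monotone
#' transform of its smoothed values.
#'
#' @inheritParams activity_matrix
#' @return Sample-by-gene score matrix (see [activity_matrix()]).
#' @export
gene_level_profile <- function(profile, alpha = 0.25, normalize = TRUE) {
  profile <- as.matrix(profile)
  if (ncol(profile) < 3) {
    abort("Need at least 3 genes.", class = "metastrat_data_error")
  }
  sets <- setNames(as.list(colnames(profile)), colnames(profile))
  activity_matrix(profile, sets, alpha = alpha, normalize = normalize)
}
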