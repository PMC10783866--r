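#' Drop samples without usable survival data and align the mutation matrix
#'
#' Removes clinical records lacking an overall-survival time or event
#' status, then inner-joins the mutation matrix to the surviving records.
#' Mutation rows without a clinical record (and vice versa) are dropped with
#' a reported count.
#'
#' @param mutations Binary sample-by-gene matrix.
#' @param records Clinical tibble (`sample_id`, `os_months`, `os_event`,
#'   ...).
#' @param quiet Suppress count messages.
#' @return List with aligned `mutations` and `records` (same sample order).
#' @export
filter_cohort <- function(mutations, records, quiet = FALSE) {
  mutations <- as_mutation_matrix(mutations)
  records <- tibble::as_tibble(records)
  n_in <- nrow(records)
  records <- dplyr::filter(records, !is.na(.data$os_months),
                           !is.na(.data$os_event))
  n_missing <- n_in - nrow(records)
  common <- intersect(rownames(mutations), records$sample_id)
  n_unmatched <- (nrow(mutations) - length(common)) +
    (nrow(records) - length(common))
  if (length(common) == 0) {
    abort("No samples remain after filtering.", class = "metastrat_data_error")
  }
  if (!quiet) {
    inform(sprintf(
      "Cohort filter: %d record(s) lacked survival data; %d unmatched id(s); %d retained.",
      n_missing, n_unmatched, length(common)))
  }
  if (n_unmatched > 0) {
    warn(sprintf("%d sample id(s) present in only one input were dropped.",
                 n_unmatched))
  }
  records <- records[match(common, records$sample_id), ]
  records <- as_survival_records(records)
  list(mutations = mutations[common, , drop = FALSE], records = records)
}

#' Training/testing split by standard-normal sorting
#'
#' Draws one standard-normal number per patient, sorts descending, and takes
#' the top `n_train` as the training cohort; the remainder form the testing
#' cohort. Equivalent to a seeded uniform split, implemented literally in
#' this form.
#'
#' @param records Clinical tibble with `sample_id`.
#' @param n_train Training-cohort size (< number of samples).
#' @param seed Integer seed.
#' @return A list of class `cohort_split`: `training`, `testing` (character
#'   id vectors), `n_train`, `seed`, `method`.
#' @export
split_cohort <- function(records, n_train, seed = 1) {
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  if (n_train >= n || n_train < 1) {
    abort("`n_train` must be in [1, n_samples).", class = "metastrat_config_error")
  }
  with_seed(child_seed(seed, "split"), {
    z <- rnorm(n)
    ord <- order(z, decreasing = TRUE)
    structure(list(
      training = records$sample_id[ord[seq_len(n_train)]],
      testing = records$sample_id[ord[-seq_len(n_train)]],
      n_train = as.integer(n_train), seed = as.integer(seed),
      method = "standard-normal descending sort"
    ), class = "cohort_split")
  })
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split> %d training / %d testing (seed %d)\n",
              length(x$training), length(x$testing), x$seed))
  invisible(x)
}

#' Orient two-cluster labels by prognosis
#'
#' Relabels a k = 2 assignment so that cluster 1 is the poor-prognosis
#' subtype (lower Kaplan-Meier median survival); if the medians tie (both
#' possibly unreached), the larger cluster becomes cluster 1. Applying the
#' orientation twice equals applying it once. For k != 2 the labels are
#' returned unchanged with a note.
#'
#' @param assignment A `cluster_assignment` (or tibble with `sample_id`,
#'   `cluster`).
#' @param records Clinical tibble covering the assigned samples.
#' @return The assignment with possibly swapped cluster labels; attribute
#'   `oriented = TRUE` when orientation was applied.
#' @export
orient_cluster_labels <- function(assignment, records) {
  ks <- sort(unique(assignment$cluster))
  if (length(ks) != 2) {
    inform("Orientation applies only to k = 2; labels returned unchanged.")
    return(assignment)
  }
  records <- as_survival_records(records)
  rec <- records[match(assignment$sample_id, records$sample_id), ]
  if (anyNA(rec$sample_id)) {
    abort("Clinical records missing for some assigned samples.",
          class = "metastrat_data_error")
  }
  km <- km_estimate(rec, assignment$cluster)
  med <- attr(km, "medians")[as.character(ks)]
  sizes <- table(factor(assignment$cluster, levels = ks))
  med[is.na(med)] <- Inf  # median never reached = best possible prognosis
  worse <- if (med[1] != med[2]) {
    ks[which.min(med)]
  } else {
    ks[which.max(sizes)]
  }
  new_cluster <- ifelse(assignment$cluster == worse, 1L, 2L)
  out <- assignment
  out$cluster <- new_cluster
  attr(out, "oriented") <- TRUE
  out
}
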