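#' Bootstrap patients with their survival records
#'
#' Draws `n` patients with replacement; mutation rows and clinical records
#' travel together. Repeated draws of the same patient get a `.k` suffix on
#' the sample id so ids stay unique.
#'
#' @param mutations Binary sample-by-gene matrix.
#' @param records Clinical tibble aligned by `sample_id`.
#' @param seed Integer seed.
#' @return List: `mutations`, `records`, `indices` (the bootstrap draw).
#' @export
bootstrap_patients <- function(mutations, records, seed = 1) {
  mutations <- as_mutation_matrix(mutations)
  records <- tibble::as_tibble(records)
  n <- nrow(mutations)
  if (n < 2) {
    abort("Need at least 2 samples to bootstrap.", class = "metastrat_data_error")
  }
  if (!identical(sort(rownames(mutations)), sort(records$sample_id))) {
    abort("Mutation rows and clinical records must cover the same samples.",
          class = "metastrat_data_error")
  }
  records <- records[match(rownames(mutations), records$sample_id), ]
  with_seed(child_seed(seed, "bootstrap"), {
    idx <- sample.int(n, n, replace = TRUE)
    ids <- rownames(mutations)[idx]
    dup_suffix <- stats::ave(seq_along(ids), ids, FUN = seq_along)
    new_ids <- ifelse(dup_suffix > 1, paste0(ids, ".", dup_suffix - 1), ids)
    m <- mutations[idx, , drop = FALSE]
    rownames(m) <- new_ids
    rec <- records[idx, ]
    rec$sample_id <- new_ids
    list(mutations = m, records = rec, indices = idx)
  })
}

#' Randomize mutations within each patient
#'
#' For every patient independently, reassigns that patient's mutations to
#' genes drawn uniformly without replacement across the whole panel. Each
#' row's mutation count is preserved exactly; per-gene frequencies are
#' destroyed, producing a mutation matrix devoid of gene-level biological
#' signal.
#'
#' @param mutations Binary sample-by-gene matrix.
#' @param seed Integer seed.
#' @return A `randomized_profile`: binary matrix of the same shape, with
#'   attribute `seed`.
#' @export
permute_within_patients <- function(mutations, seed = 1) {
  mutations <- as_mutation_matrix(mutations)
  n_genes <- ncol(mutations)
  with_seed(child_seed(seed, "permute"), {
    out <- mutations * 0
    counts <- rowSums(mutations)
    for (s in seq_len(nrow(mutations))) {
      m <- counts[s]
      if (m > 0) out[s, sample.int(n_genes, m)] <- 1
    }
    attr(out, "seed") <- as.integer(seed)
    class(out) <- c("randomized_profile", class(out))
    out
  })
}

#' Build the randomized-mutation null cohort
#'
#' The null construction used to show the pipeline finds no subtype signal
#' absent biology: bootstrap patients (with their survival records), then
#' permute each patient's mutations across the panel, preserving per-patient
#' mutation frequency.
#'
#' @inheritParams bootstrap_patients
#' @return List: `mutations` (randomized profile), `records`,
#'   `bootstrap_indices`, `seed`.
#' @export
randomize_cohort <- function(mutations, records, seed = 1) {
  bs <- bootstrap_patients(mutations, records, seed = seed)
  rp <- permute_within_patients(bs$mutations, seed = child_seed(seed, "rp"))
  list(mutations = rp, records = bs$records,
       bootstrap_indices = bs$indices, seed = as.integer(seed))
}
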