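#' Run code under a locally fixed RNG seed
#'
#' Evaluates `expr` with the RNG state set from `seed`, restoring the caller's
#' RNG state afterwards so library code never perturbs the user's stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a base seed and a stage label
#'
#' Deterministic and label-dependent so independent pipeline stages draw from
#' unrelated streams. Always returns a positive integer below 2^31.
#' @noRd
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h * 69621) %% 2147483399) + 1L
}

assert_binary_matrix <- function(x, arg = "mutations") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg), class = "metastrat_data_error")
  }
  if (!all(x %in% c(0, 1))) {
    abort(sprintf("`%s` must contain only 0/1 entries.", arg),
          class = "metastrat_data_error")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("`%s` must carry sample rownames and gene colnames.", arg),
          class = "metastrat_data_error")
  }
  invisible(x)
}

#' Read a gene-set collection from a GMT file
#'
#' One set per line: name, description, then tab-separated gene ids.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene ids, with a
#'   `"provenance"` attribute recording the source path.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("GMT file not found: %s", path), class = "metastrat_config_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", bad[1]),
          class = "metastrat_data_error")
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) {
    abort("Duplicate gene-set names in GMT.", class = "metastrat_data_error")
  }
  attr(sets, "provenance") <- path
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Named list of character vectors of gene ids.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "metastrat") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a numeric matrix as TSV with a `sample_id` index column
#' @noRd
write_matrix_tsv <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "sample_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a matrix TSV written by [write_matrix_tsv()]
#' @noRd
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
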