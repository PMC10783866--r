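#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Cox fit
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return A plain tibble with one row per model term.
#' @export
tidy.cox_fit <- function(x, ...) {
  tibble::as_tibble(as.data.frame(unclass(x)))
}

#' One-row model summary of a Cox fit
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return Tibble with `n`, `n_event`, `loglik`, `score_statistic`.
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = attr(x, "n"), n_event = attr(x, "n_event"),
                 loglik = attr(x, "loglik"),
                 score_statistic = attr(x, "score_statistic"))
}

#' Tidy a prognostic screen
#'
#' @param x A `cox_screen`.
#' @param ... Unused.
#' @return Plain tibble, one row per pathway.
#' @export
tidy.cox_screen <- function(x, ...) {
  tibble::as_tibble(as.data.frame(unclass(x)))
}

#' One-row summary of a prognostic screen
#'
#' @param x A `cox_screen`.
#' @param ... Unused.
#' @return Tibble with pathway counts by direction and the screen alpha.
#' @export
glance.cox_screen <- function(x, ...) {
  tibble::tibble(
    n_pathways = nrow(x),
    n_retained = sum(x$retained),
    n_risk = sum(x$retained & x$direction == "risk"),
    n_protective = sum(x$retained & x$direction == "protective"),
    alpha = attr(x, "alpha")
  )
}

#' Tidy a cluster assignment
#'
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @return Plain tibble `sample_id`, `cluster`, `silhouette`.
#' @export
tidy.cluster_assignment <- function(x, ...) {
  tibble::as_tibble(as.data.frame(unclass(x)))
}

#' One-row summary of a cluster assignment
#'
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @return Tibble with `k`, `avg_silhouette` and cluster sizes.
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble::tibble(
    k = attr(x, "k"),
    avg_silhouette = attr(x, "avg_silhouette"),
    min_cluster_size = min(table(x$cluster)),
    max_cluster_size = max(table(x$cluster))
  )
}

#' Tidy a Kaplan-Meier fit
#'
#' @param x A `km_fit`.
#' @param ... Unused.
#' @return Plain tibble of the survival steps.
#' @export
tidy.km_fit <- function(x, ...) {
  tibble::as_tibble(as.data.frame(unclass(x)))
}
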