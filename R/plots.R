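#' Kaplan-Meier step curves
#'
#' @param object A `km_fit` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_fit <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, survival = 1), .x[, c("time", "survival")])) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' Silhouette plot of a cluster assignment
#'
#' Per-sample silhouette widths ordered within clusters, with the average
#' width as a reference line.
#'
#' @param object A `cluster_assignment` from [train_sdcn()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_assignment <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::arrange(.data$cluster, dplyr::desc(.data$silhouette)) |>
    dplyr::mutate(pos = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(.data$pos, .data$silhouette,
                                   fill = factor(.data$cluster))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = attr(object, "avg_silhouette"),
                        linetype = "dashed") +
    ggplot2::labs(x = "Samples (ordered within cluster)",
                  y = "Silhouette width", fill = "Cluster") +
    ggplot2::theme_minimal()
}

#' Forest plot of a prognostic screen
#'
#' Hazard ratios with 95% confidence intervals of the retained pathways
#' (log scale), coloured by direction.
#'
#' @param object A `cox_screen` from [screen_prognostic_pathways()].
#' @param retained_only Plot only pathways passing the screen.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cox_screen <- function(object, retained_only = TRUE, ...) {
  df <- tidy(object)
  if (retained_only) df <- dplyr::filter(df, .data$retained)
  df <- dplyr::mutate(df, pathway = stats::reorder(.data$pathway,
                                                   .data$hazard_ratio))
  ggplot2::ggplot(df, ggplot2::aes(.data$hazard_ratio, .data$pathway,
                                   colour = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.25) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL,
                  colour = "Direction") +
    ggplot2::theme_minimal()
}

#' Silhouette-vs-k curve of a cluster-number selection
#'
#' @param object An `sdcn_selection` from [select_n_clusters()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sdcn_selection <- function(object, ...) {
  ggplot2::ggplot(object$silhouettes,
                  ggplot2::aes(.data$k, .data$avg_silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = dplyr::filter(object$silhouettes,
                                             .data$k == object$best_k),
                        colour = "red", size = 3) +
    ggplot2::scale_x_continuous(breaks = object$silhouettes$k) +
    ggplot2::labs(x = "Number of clusters k",
                  y = "Average silhouette width") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
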