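#' Validate a clinical records table
#' @noRd
as_survival_records <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("sample_id", "os_months", "os_event")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(paste0("Clinical table lacks column(s): ",
                 paste(miss, collapse = ", ")),
          class = "metastrat_data_error")
  }
  if (any(!is.na(records$os_months) & records$os_months <= 0)) {
    abort("Survival times must be positive.", class = "metastrat_data_error")
  }
  ev <- records$os_event[!is.na(records$os_event)]
  if (!all(ev %in% c(0, 1))) {
    abort("`os_event` must be 0 (censored) or 1 (death).",
          class = "metastrat_data_error")
  }
  records
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator `S(t) = prod(1 - d_i / n_i)` over distinct event
#' times, overall or per group. Censored observations leave the risk set
#' without producing a step.
#'
#' @param records Clinical tibble with `sample_id`, `os_months`, `os_event`.
#' @param group_labels Optional vector (or name of a column in `records`)
#'   defining groups.
#' @return A tibble of class `km_fit` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`, plus a `medians` attribute
#'   (per-group median survival).
#' @export
km_estimate <- function(records, group_labels = NULL) {
  records <- as_survival_records(records)
  g <- resolve_groups(records, group_labels)
  if (any(table(g) < 1) || nrow(records) == 0) {
    abort("Each group needs at least one record.", class = "metastrat_data_error")
  }
  fit <- if (length(unique(g)) > 1) {
    survival::survfit(survival::Surv(os_months, os_event) ~ g,
                      data = cbind(records, g = g))
  } else {
    survival::survfit(survival::Surv(os_months, os_event) ~ 1, data = records)
  }
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(as.character(g)), length(s$time)) else
    sub("^g=", "", as.character(s$strata))
  out <- tibble::tibble(
    group = grp, time = s$time, n_risk = s$n.risk,
    n_event = s$n.event, n_censor = s$n.censor, survival = s$surv
  )
  med <- summary(fit)$table
  medians <- if (is.null(dim(med))) {
    setNames(med[["median"]], unique(grp))
  } else {
    setNames(med[, "median"], sub("^g=", "", rownames(med)))
  }
  attr(out, "medians") <- medians
  class(out) <- c("km_fit", class(out))
  out
}

resolve_groups <- function(records, group_labels) {
  if (is.null(group_labels)) return(rep("all", nrow(records)))
  if (is.character(group_labels) && length(group_labels) == 1 &&
      group_labels %in% names(records)) {
    return(as.character(records[[group_labels]]))
  }
  if (length(group_labels) != nrow(records)) {
    abort("`group_labels` length must match the records.",
          class = "metastrat_data_error")
  }
  as.character(group_labels)
}

#' Log-rank test between survival groups
#'
#' Observed-minus-expected chi-square statistic over pooled event times with
#' `groups - 1` degrees of freedom.
#'
#' @inheritParams km_estimate
#' @param group_labels Group labels (vector or column name); >= 2 nonempty
#'   groups required.
#' @return A list: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(records, group_labels) {
  records <- as_survival_records(records)
  g <- resolve_groups(records, group_labels)
  if (length(unique(g)) < 2) {
    abort("Log-rank needs at least two groups.", class = "metastrat_data_error")
  }
  sd <- survival::survdiff(survival::Surv(os_months, os_event) ~ g,
                           data = cbind(records, g = g))
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p_value = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Breslow-tie partial-likelihood maximization (Newton iterations via
#' `survival::coxph`). Reports per-covariate hazard ratios with Wald 95%
#' confidence intervals `exp(coef +/- 1.96 SE)`. Categorical covariates are
#' coded against their most frequent level. Convergence problems or
#' infinite coefficients are flagged, never silent.
#'
#' @inheritParams km_estimate
#' @param covariates Character vector of column names in `records` (one for
#'   univariate, several for multivariate), or a data frame / matrix of
#'   covariate values aligned to `records`.
#' @return A tibble of class `cox_fit`: `term`, `coef`, `se`,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `p_value`, `flagged`; attributes
#'   `loglik`, `n`, `n_event`, `score_statistic` (the score test at beta =
#'   0, which for a single binary covariate equals the two-group log-rank
#'   statistic).
#' @export
cox_fit <- function(records, covariates) {
  records <- as_survival_records(records)
  if (sum(records$os_event) < 1) {
    abort("Cox fit needs at least one event.", class = "metastrat_data_error")
  }
  X <- if (is.character(covariates)) {
    miss <- setdiff(covariates, names(records))
    if (length(miss) > 0) {
      abort(paste0("Unknown covariate(s): ", paste(miss, collapse = ", ")),
            class = "metastrat_data_error")
    }
    records[, covariates, drop = FALSE]
  } else {
    tibble::as_tibble(as.data.frame(covariates))
  }
  X <- dplyr::mutate(X, dplyr::across(
    dplyr::where(~ is.character(.x) || is.factor(.x)),
    ~ {
      f <- as.factor(.x)
      stats::relevel(f, ref = names(which.max(table(f))))
    }))
  const <- vapply(X, function(v) length(unique(v[!is.na(v)])) < 2, logical(1))
  if (any(const)) {
    abort(paste0("Constant covariate(s): ",
                 paste(names(X)[const], collapse = ", ")),
          class = "metastrat_data_error")
  }
  dat <- cbind(records[, c("os_months", "os_event")], X)
  fml <- stats::as.formula(paste(
    "survival::Surv(os_months, os_event) ~",
    paste(sprintf("`%s`", names(X)), collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "breslow"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  if (any(!is.finite(co[, "coef"])) || any(abs(co[, "coef"]) > 20)) {
    flagged <- TRUE
  }
  out <- tibble::tibble(
    term = rownames(co),
    coef = co[, "coef"],
    se = co[, "se(coef)"],
    hazard_ratio = exp(co[, "coef"]),
    ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
    ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
    p_value = co[, "Pr(>|z|)"],
    flagged = flagged
  )
  attr(out, "loglik") <- unname(fit$loglik[2])
  attr(out, "n") <- fit$n
  attr(out, "n_event") <- fit$nevent
  attr(out, "score_statistic") <- unname(sm$sctest["test"])
  class(out) <- c("cox_fit", class(out))
  out
}

#' Screen pathways for prognostic association
#'
#' One univariate Cox fit of overall survival on each pathway-activity
#' column; pathways with Wald p below `alpha` are retained and labelled
#' `"risk"` (hazard ratio > 1: higher activity, shorter survival) or
#' `"protective"`. No multiplicity correction is applied by default;
#' `adjust = "BH"` adds a false-discovery-rate column and screens on it.
#'
#' @param activity Sample-by-pathway numeric matrix (samples as rownames)
#'   or tibble with a `sample_id` first column.
#' @param records Clinical tibble; joined to `activity` on `sample_id`.
#' @param alpha Retention threshold on the p-value.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble of class `cox_screen` (one row per pathway, ordered by
#'   p): `pathway`, `coef`, `hazard_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   (`p_adjusted`,) `direction`, `retained`. Attribute `alpha`.
#' @export
screen_prognostic_pathways <- function(activity, records, alpha = 0.05,
                                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.data.frame(activity)) {
    m <- as.matrix(activity[, -1, drop = FALSE])
    rownames(m) <- as.character(activity[[1]])
    activity <- m
  }
  records <- as_survival_records(records)
  common <- intersect(rownames(activity), records$sample_id)
  if (length(common) < 3) {
    abort("Too few samples shared between activity and records.",
          class = "metastrat_data_error")
  }
  activity <- activity[common, , drop = FALSE]
  records <- records[match(common, records$sample_id), ]

  rows <- purrr::map(colnames(activity), function(pw) {
    fit <- cox_fit(records, setNames(tibble::tibble(x = activity[, pw]), pw))
    dplyr::mutate(fit[1, c("coef", "hazard_ratio", "ci_low", "ci_high",
                           "p_value", "flagged")],
                  pathway = pw, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  p_screen <- out$p_value
  if (adjust == "BH") {
    out$p_adjusted <- p.adjust(out$p_value, method = "BH")
    p_screen <- out$p_adjusted
  }
  out <- out |>
    dplyr::mutate(
      direction = ifelse(.data$hazard_ratio > 1, "risk", "protective"),
      retained = p_screen < alpha
    ) |>
    dplyr::arrange(.data$p_value)
  if (!any(out$retained)) {
    warn("No pathway passed the prognostic screen.")
  }
  attr(out, "alpha") <- alpha
  class(out) <- c("cox_screen", class(out))
  out
}
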