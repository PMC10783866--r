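#' Pipeline configuration
#'
#' Bundles input paths and stage parameters for [run_pipeline()] /
#' [run_null_pipeline()]. All referenced files must exist when the config is
#' built.
#'
#' @param edges,mutations,clinical,gmt Paths to the edge-list TSV, binary
#'   mutation TSV, clinical TSV and gene-set GMT.
#' @param out_dir Output directory for intermediates and the manifest.
#' @param score_threshold Interaction-score cutoff for [load_network()].
#' @param rwr [rwr_params()].
#' @param ssgsea_alpha Rank-weight exponent of the enrichment statistic.
#' @param normalize Normalize activity scores per cohort (see
#'   [activity_matrix()]).
#' @param screening_alpha Retention p-value threshold of the prognostic
#'   screen.
#' @param sdcn [sdcn_config()].
#' @param k_range Candidate cluster numbers.
#' @param n_train Training-cohort size: an integer count, or a fraction in
#'   (0, 1) of the filtered cohort.
#' @param seed Integer master seed (stage seeds are derived from it).
#' @param fallback_to_all_pathways If no pathway passes the screen, cluster
#'   on all pathway columns instead of failing (used by the null pipeline).
#' @param persist `"full"` writes every intermediate including smoothed
#'   profiles; `"light"` skips the large matrices.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(edges, mutations, clinical, gmt, out_dir,
                            score_threshold = 700, rwr = rwr_params(),
                            ssgsea_alpha = 0.25, normalize = TRUE,
                            screening_alpha = 0.05, sdcn = sdcn_config(),
                            k_range = 2:10, n_train = 0.75, seed = 1,
                            fallback_to_all_pathways = FALSE,
                            persist = c("full", "light")) {
  persist <- match.arg(persist)
  paths <- c(edges = edges, mutations = mutations, clinical = clinical,
             gmt = gmt)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("Input file(s) not found: ",
                 paste(missing, collapse = ", ")),
          class = "metastrat_config_error")
  }
  structure(list(
    edges = edges, mutations = mutations, clinical = clinical, gmt = gmt,
    out_dir = out_dir, score_threshold = score_threshold, rwr = rwr,
    ssgsea_alpha = ssgsea_alpha, normalize = normalize,
    screening_alpha = screening_alpha, sdcn = sdcn, k_range = k_range,
    n_train = n_train, seed = as.integer(seed),
    fallback_to_all_pathways = fallback_to_all_pathways,
    persist = persist
  ), class = "pipeline_config")
}

resolve_n_train <- function(n_train, n) {
  if (n_train > 0 && n_train < 1) n_train <- round(n_train * n)
  as.integer(n_train)
}

#' Run the full stratification pipeline
#'
#' Stages, in order: cohort filtering; standard-normal-sort training/testing
#' split; random-walk smoothing of mutation profiles over the interaction
#' network; pathway-activity scoring (normalized per cohort); univariate-Cox
#' prognostic screening in the training cohort; SDCN clustering of the
#' training cohort on the retained pathways with silhouette selection of k;
#' prognosis-based label orientation; Kaplan-Meier / log-rank / Cox
#' validation; and re-clustering of the testing cohort with the
#' training-derived pathway list. Every intermediate is written to
#' `config$out_dir` together with a JSON manifest of seeds, parameters and
#' output-file hashes.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `metastrat_result` (see the vignette for the
#'   components).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  network <- load_network(config$edges, config$score_threshold, quiet = TRUE)
  gmt <- read_gmt(config$gmt)
  mutations <- read_matrix_tsv(config$mutations)
  clinical <- readr::read_tsv(config$clinical, show_col_types = FALSE,
                              progress = FALSE)

  flt <- filter_cohort(mutations, clinical, quiet = TRUE)
  n_train <- resolve_n_train(config$n_train, nrow(flt$records))
  split <- split_cohort(flt$records, n_train, seed = config$seed)

  smoothed <- smooth_profile(flt$mutations, network, config$rwr,
                             on_unmapped_sample = "exclude")
  cohorts <- analyse_cohorts(smoothed, flt$records, split, gmt, config)

  paths <- persist_results(cohorts, smoothed, split, config)
  manifest <- build_manifest(config, split, cohorts, paths)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(c(cohorts, list(split = split, manifest = manifest,
                            paths = paths, config = config)),
            class = "metastrat_result")
}

# Training-cohort screening + clustering, then testing-cohort re-clustering
# with the training-derived pathway list.
analyse_cohorts <- function(smoothed, records, split, gmt, config) {
  train_ids <- intersect(split$training, rownames(smoothed))
  test_ids <- intersect(split$testing, rownames(smoothed))
  rec_train <- records[match(train_ids, records$sample_id), ]
  rec_test <- records[match(test_ids, records$sample_id), ]

  act_train <- activity_matrix(smoothed[train_ids, , drop = FALSE], gmt,
                               alpha = config$ssgsea_alpha,
                               normalize = config$normalize)
  screen <- screen_prognostic_pathways(act_train, rec_train,
                                       alpha = config$screening_alpha)
  prognostic <- screen$pathway[screen$retained]
  used_fallback <- FALSE
  if (length(prognostic) < 1) {
    if (!config$fallback_to_all_pathways) {
      abort("No prognostic pathway retained; cannot cluster.",
            class = "metastrat_data_error")
    }
    inform("Prognostic screen empty; clustering on all pathways.")
    prognostic <- colnames(act_train)
    used_fallback <- TRUE
  }

  sel_train <- select_n_clusters(act_train[, prognostic, drop = FALSE],
                                 config = config$sdcn,
                                 k_range = config$k_range)
  assign_train <- orient_cluster_labels(sel_train$assignment, rec_train)
  km_train <- km_estimate(rec_train, assign_train$cluster)
  lr_train <- logrank_test(rec_train, assign_train$cluster)
  cox_train <- subtype_cox(rec_train, assign_train)

  test_res <- NULL
  if (length(test_ids) > max(config$k_range)) {
    act_test <- activity_matrix(smoothed[test_ids, , drop = FALSE], gmt,
                                alpha = config$ssgsea_alpha,
                                normalize = config$normalize)
    keep <- intersect(prognostic, colnames(act_test))
    sel_test <- select_n_clusters(act_test[, keep, drop = FALSE],
                                  config = config$sdcn,
                                  k_range = config$k_range)
    assign_test <- orient_cluster_labels(sel_test$assignment, rec_test)
    test_res <- list(
      selection = sel_test, assignment = assign_test,
      km = km_estimate(rec_test, assign_test$cluster),
      logrank = logrank_test(rec_test, assign_test$cluster),
      activity = act_test, records = rec_test
    )
  }

  list(screen = screen, prognostic_pathways = prognostic,
       used_fallback = used_fallback,
       selection = sel_train, assignment = assign_train,
       km = km_train, logrank = lr_train, cox = cox_train,
       activity = act_train, records = rec_train, testing = test_res)
}

# Univariate Cox on the subtype label; multivariate when the clinical table
# carries extra covariates.
subtype_cox <- function(records, assignment) {
  rec <- records[match(assignment$sample_id, records$sample_id), ]
  rec$cluster <- factor(assignment$cluster)
  uni <- cox_fit(rec, "cluster")
  extra <- setdiff(names(rec),
                   c("sample_id", "os_months", "os_event", "subtype_true",
                     "cluster"))
  extra <- extra[vapply(rec[extra], function(v)
    length(unique(v[!is.na(v)])) > 1, logical(1))]
  multi <- if (length(extra) > 0) {
    tryCatch(cox_fit(rec, c("cluster", extra)), error = function(e) NULL)
  }
  list(univariate = uni, multivariate = multi)
}

persist_results <- function(cohorts, smoothed, split, config) {
  od <- config$out_dir
  p <- character(0)
  wr <- function(x, name, writer = readr::write_tsv) {
    fp <- file.path(od, name)
    writer(x, fp)
    p[[name]] <<- fp
  }
  if (config$persist == "full") {
    wr(unclass_matrix(smoothed), "smoothed_profile.tsv", write_matrix_tsv)
    wr(cohorts$activity, "activity_training.tsv", write_matrix_tsv)
    if (!is.null(cohorts$testing)) {
      wr(cohorts$testing$activity, "activity_testing.tsv", write_matrix_tsv)
    }
  }
  wr(tibble::tibble(sample_id = c(split$training, split$testing),
                    cohort = rep(c("training", "testing"),
                                 c(length(split$training),
                                   length(split$testing)))),
     "split.tsv")
  wr(as_plain_tibble(cohorts$screen), "prognostic_screen.tsv")
  wr(as_plain_tibble(cohorts$assignment), "assignment_training.tsv")
  wr(as_plain_tibble(cohorts$km), "km_training.tsv")
  wr(cohorts$selection$silhouettes, "silhouettes_training.tsv")
  if (!is.null(cohorts$testing)) {
    wr(as_plain_tibble(cohorts$testing$assignment), "assignment_testing.tsv")
    wr(as_plain_tibble(cohorts$testing$km), "km_testing.tsv")
    wr(cohorts$testing$selection$silhouettes, "silhouettes_testing.tsv")
  }
  p
}

unclass_matrix <- function(m) {
  attrs <- names(attributes(m))
  for (a in setdiff(attrs, c("dim", "dimnames"))) attr(m, a) <- NULL
  m
}

as_plain_tibble <- function(x) {
  out <- tibble::as_tibble(as.data.frame(unclass(x)))
  out
}

build_manifest <- function(config, split, cohorts, paths) {
  hashes <- as.list(tools::md5sum(unlist(paths)))
  names(hashes) <- names(paths)
  list(
    package = "metastrat",
    version = as.character(utils::packageVersion("metastrat")),
    seed = config$seed,
    parameters = list(
      score_threshold = config$score_threshold,
      rwr = unclass(config$rwr),
      ssgsea_alpha = config$ssgsea_alpha,
      normalize = config$normalize,
      screening_alpha = config$screening_alpha,
      sdcn = unclass(config$sdcn),
      k_range = config$k_range,
      n_train = config$n_train
    ),
    inputs = list(edges = config$edges, mutations = config$mutations,
                  clinical = config$clinical, gmt = config$gmt),
    n_training = length(split$training),
    n_testing = length(split$testing),
    n_prognostic_pathways = length(cohorts$prognostic_pathways),
    used_fallback = cohorts$used_fallback,
    best_k_training = cohorts$selection$best_k,
    logrank_p_training = cohorts$logrank$p_value,
    logrank_p_testing = if (!is.null(cohorts$testing))
      cohorts$testing$logrank$p_value,
    output_hashes = hashes
  )
}

#' @export
print.metastrat_result <- function(x, ...) {
  cat("<metastrat_result>\n")
  cat(sprintf("  training: n = %d, k = %d, %d prognostic pathways, log-rank p = %.3g\n",
              nrow(x$assignment), x$selection$best_k,
              length(x$prognostic_pathways), x$logrank$p_value))
  if (!is.null(x$testing)) {
    cat(sprintf("  testing:  n = %d, k = %d, log-rank p = %.3g\n",
                nrow(x$testing$assignment), x$testing$selection$best_k,
                x$testing$logrank$p_value))
  }
  invisible(x)
}

#' Run the pipeline on a randomized (null) cohort
#'
#' Builds the randomized mutation matrix — patient bootstrap followed by
#' within-patient permutation across the gene panel — and runs smoothing,
#' scoring, screening and SDCN clustering at a fixed k on the whole
#' randomized cohort (no training/testing split: the null asks whether any
#' subtype signal survives randomization). When the screen retains no
#' pathway, clustering falls back to all pathway columns so a subtype split
#' and its log-rank p-value are still produced.
#'
#' @param config A [pipeline_config()].
#' @param k Cluster number for the null run (default 2, the k found on real
#'   data).
#' @return A list of class `metastrat_null_result`: `logrank_p`,
#'   `n_prognostic_pathways`, `used_fallback`, `assignment`, `screen`,
#'   `seeds`.
#' @export
run_null_pipeline <- function(config, k = 2) {
  stopifnot(inherits(config, "pipeline_config"))
  network <- load_network(config$edges, config$score_threshold, quiet = TRUE)
  gmt <- read_gmt(config$gmt)
  mutations <- read_matrix_tsv(config$mutations)
  clinical <- readr::read_tsv(config$clinical, show_col_types = FALSE,
                              progress = FALSE)
  flt <- filter_cohort(mutations, clinical, quiet = TRUE)

  nullc <- randomize_cohort(flt$mutations, flt$records,
                            seed = child_seed(config$seed, "null"))
  smoothed <- smooth_profile(nullc$mutations, network, config$rwr,
                             on_unmapped_sample = "exclude")
  act <- activity_matrix(smoothed, gmt, alpha = config$ssgsea_alpha,
                         normalize = config$normalize)
  rec <- nullc$records[match(rownames(act), nullc$records$sample_id), ]
  screen <- suppressWarnings(
    screen_prognostic_pathways(act, rec, alpha = config$screening_alpha))
  prognostic <- screen$pathway[screen$retained]
  used_fallback <- length(prognostic) < 1
  if (used_fallback) prognostic <- colnames(act)

  cfg_k <- config$sdcn
  cfg_k$n_clusters <- as.integer(k)
  assignment <- train_sdcn(act[, prognostic, drop = FALSE], config = cfg_k)
  assignment <- orient_cluster_labels(assignment, rec)
  lr <- logrank_test(rec, assignment$cluster)

  structure(list(
    logrank_p = lr$p_value,
    n_prognostic_pathways = sum(screen$retained),
    used_fallback = used_fallback,
    assignment = assignment, screen = screen,
    seeds = list(master = config$seed,
                 null = child_seed(config$seed, "null"))
  ), class = "metastrat_null_result")
}

#' Write a ready-to-run synthetic demo dataset
#'
#' Generates a demo-scale cohort (defaults: 500 patients, 1000 genes, 20
#' pathways of 25-35 genes of which 10 are informative, with a dense planted
#' mutational signal) and writes the four pipeline inputs (edge list,
#' mutation matrix, clinical table, GMT) to `dir`. The clinical table
#' carries the planted subtype in `subtype_true` for benchmarking. The demo
#' plants a deliberately strong signal so subtype recovery is achievable at
#' this cohort size; see the vignette for what that does and does not show.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_samples,n_genes,n_pathways,n_informative_pathways Demo scale.
#' @param baseline_mutation_rate Per-gene mutation probability.
#' @param ... Further arguments to [synthetic_spec()].
#' @return Invisibly, a list with the file `paths` and the `spec`.
#' @export
make_demo <- function(dir, seed = 1, n_samples = 500, n_genes = 1000,
                      n_pathways = 20, n_informative_pathways = 10,
                      baseline_mutation_rate = 0.05,
                      pathway_size_range = c(25, 35), ...) {
  spec <- synthetic_spec(n_genes = n_genes, n_samples = n_samples,
                         n_pathways = n_pathways,
                         pathway_size_range = pathway_size_range,
                         n_informative_pathways = n_informative_pathways,
                         baseline_mutation_rate = baseline_mutation_rate,
                         seed = seed, ...)
  network <- generate_network(spec)
  pathways <- generate_pathways(network, spec)
  cohort <- generate_cohort(network, pathways, spec)
  paths <- write_cohort(cohort, network, pathways, dir)
  invisible(list(paths = paths, spec = spec))
}
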