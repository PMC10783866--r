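#' Specification for a synthetic mutation cohort
#'
#' Fixes every knob of the generator: gene universe, pathway collection
#' shape, mutation sparsity, the planted two-subtype structure (mutation
#' enrichment of informative-pathway genes in subtype A) and a
#' proportional-hazards survival link. Defaults describe a benchmark cohort
#' chosen for planted-signal recoverability rather than clinical sparsity:
#' 8000 genes at a 2.5% per-gene mutation rate, 114 nearly disjoint
#' network-separated pathways of 15-40 genes, a threefold mutation-rate
#' enrichment in 10 informative pathways, and a log hazard ratio of 0.7
#' between subtypes with ~30% censoring. Real targeted-panel cohorts are
#' far sparser; see the vignette for what this benchmark does and does not
#' emulate.
#'
#' @param n_genes Number of genes in the universe (>= 10).
#' @param n_samples Number of patients.
#' @param n_pathways Number of gene sets.
#' @param pathway_size_range Length-2 integer range of set sizes.
#' @param n_informative_pathways Number of pathways whose genes are
#'   mutation-enriched in subtype A (<= `n_pathways`).
#' @param baseline_mutation_rate Per-gene mutation probability in (0, 1).
#' @param enrichment_factor Multiplier (>= 1) on the mutation rate of
#'   informative-pathway genes for subtype-A patients.
#' @param subtype_proportion Fraction of patients in subtype A, in (0, 1).
#' @param hazard_log_ratio Log hazard ratio of subtype A vs B.
#' @param censoring_rate Target censored fraction in (0, 1).
#' @param median_survival Baseline (subtype B) median survival in months;
#'   sets the exponential baseline hazard.
#' @param avg_degree Target mean degree of the interaction network.
#' @param seed Integer seed; a fixed seed makes the whole cohort
#'   byte-reproducible.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 8000, n_samples = 500, n_pathways = 114,
                           pathway_size_range = c(15, 40),
                           n_informative_pathways = 10,
                           baseline_mutation_rate = 0.025,
                           enrichment_factor = 3, subtype_proportion = 0.5,
                           hazard_log_ratio = 0.7, censoring_rate = 0.3,
                           median_survival = 24, avg_degree = 8, seed = 1) {
  chk <- function(ok, msg) if (!ok) abort(msg, class = "metastrat_config_error")
  chk(n_genes >= 10, "`n_genes` must be >= 10.")
  chk(baseline_mutation_rate > 0 && baseline_mutation_rate < 1,
      "`baseline_mutation_rate` must be in (0, 1).")
  chk(subtype_proportion > 0 && subtype_proportion < 1,
      "`subtype_proportion` must be in (0, 1).")
  chk(censoring_rate > 0 && censoring_rate < 1,
      "`censoring_rate` must be in (0, 1).")
  chk(enrichment_factor >= 1, "`enrichment_factor` must be >= 1.")
  chk(length(pathway_size_range) == 2 &&
        pathway_size_range[1] >= 1 &&
        pathway_size_range[1] <= pathway_size_range[2],
      "`pathway_size_range` must be an increasing pair.")
  chk(pathway_size_range[2] <= n_genes,
      "Pathway sizes cannot exceed `n_genes`.")
  chk(n_informative_pathways <= n_pathways,
      "`n_informative_pathways` must be <= `n_pathways`.")
  chk(avg_degree >= 2 && avg_degree < n_genes,
      "`avg_degree` must be in [2, n_genes).")
  structure(list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    n_informative_pathways = as.integer(n_informative_pathways),
    baseline_mutation_rate = baseline_mutation_rate,
    enrichment_factor = enrichment_factor,
    subtype_proportion = subtype_proportion,
    hazard_log_ratio = hazard_log_ratio,
    censoring_rate = censoring_rate,
    median_survival = median_survival,
    avg_degree = avg_degree, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Generate a synthetic weighted gene-interaction network
#'
#' Preferential-attachment wiring (each new gene attaches to
#' `avg_degree / 2` existing genes with probability proportional to degree)
#' yields a connected graph with a heavy-tailed degree distribution, the
#' qualitative shape of curated protein-interaction networks. Edge scores
#' are drawn uniformly in (700, 1000], the post-filter score dialect of
#' high-confidence interaction databases.
#'
#' @param spec A [synthetic_spec()].
#' @return A `gene_network` (see [load_network()]).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_genes
  m <- max(1L, as.integer(round(spec$avg_degree / 2)))
  if (n <= m + 1) {
    abort("`n_genes` too small for the requested average degree.",
          class = "metastrat_config_error")
  }
  ids <- sprintf("G%0*d", max(4L, nchar(n)), seq_len(n))
  with_seed(child_seed(spec$seed, "network"), {
    deg <- integer(n)
    from <- integer(0); to <- integer(0)
    # seed clique on the first m + 1 genes
    seed_pairs <- utils::combn(m + 1L, 2L)
    from <- seed_pairs[1, ]; to <- seed_pairs[2, ]
    deg[seq_len(m + 1)] <- m
    for (v in seq.int(m + 2L, n)) {
      existing <- seq_len(v - 1L)
      targets <- sample(existing, m, prob = deg[existing] + 1e-9)
      from <- c(from, targets); to <- c(to, rep(v, m))
      deg[targets] <- deg[targets] + 1L
      deg[v] <- m
    }
    scores <- round(runif(length(from), 700.001, 1000), 3)
    a <- pmin(from, to); b <- pmax(from, to)
    edges <- tibble::tibble(gene1 = ids[a], gene2 = ids[b], score = scores) |>
      dplyr::arrange(.data$gene1, .data$gene2)
    structure(list(genes = ids, edges = edges, score_threshold = 700),
              class = "gene_network")
  })
}

#' Generate gene sets with network locality and low reuse
#'
#' Each set grows from a seed gene by sampling graph neighbors of the
#' current set, preferring genes not yet used by other sets and not adjacent
#' to them. The result is a collection of nearly disjoint,
#' neighborhood-separated network modules, mimicking a curated
#' metabolic-pathway collection in which the union of set genes is close to
#' the sum of set sizes. The separation keeps propagation spillover from one
#' module out of the others, so pathways not planted as informative are
#' genuinely signal-free.
#'
#' @param network A `gene_network`.
#' @param spec A [synthetic_spec()].
#' @return Named list of gene-id vectors (`PW001`, ...), with attribute
#'   `provenance = "synthetic"`.
#' @export
generate_pathways <- function(network, spec) {
  stopifnot(inherits(network, "gene_network"), inherits(spec, "synthetic_spec"))
  if (spec$pathway_size_range[2] > length(network$genes)) {
    abort("Pathway sizes exceed the number of network genes.",
          class = "metastrat_config_error")
  }
  genes <- network$genes
  n <- length(genes)
  ii <- match(network$edges$gene1, genes)
  jj <- match(network$edges$gene2, genes)
  nbr <- vector("list", n)
  for (e in seq_along(ii)) {
    nbr[[ii[e]]] <- c(nbr[[ii[e]]], jj[e])
    nbr[[jj[e]]] <- c(nbr[[jj[e]]], ii[e])
  }
  with_seed(child_seed(spec$seed, "pathways"), {
    used <- rep(FALSE, n)        # in some set
    fringe <- rep(FALSE, n)      # adjacent to some set
    sets <- vector("list", spec$n_pathways)
    size_choices <- seq.int(spec$pathway_size_range[1],
                            spec$pathway_size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), spec$n_pathways,
                                     replace = TRUE)]
    for (p in seq_len(spec$n_pathways)) {
      target <- sizes[p]
      fresh <- which(!used & !fringe)
      if (length(fresh) == 0) fresh <- which(!used)
      start <- if (length(fresh) > 0) {
        fresh[sample.int(length(fresh), 1)]
      } else {
        sample.int(n, 1)
      }
      members <- start
      while (length(members) < target) {
        cand <- setdiff(unique(unlist(nbr[members])), members)
        if (length(cand) == 0) {
          cand <- setdiff(seq_len(n), members)
        }
        # near-disjoint and neighborhood-separated: strongly prefer genes
        # neither in nor adjacent to previously sampled sets
        w <- ifelse(used[cand], 1, ifelse(fringe[cand], 30, 1000))
        members <- c(members, cand[sample.int(length(cand), 1, prob = w)])
      }
      used[members] <- TRUE
      fringe[unique(unlist(nbr[members]))] <- TRUE
      sets[[p]] <- sort(genes[members])
    }
    names(sets) <- sprintf("PW%03d", seq_len(spec$n_pathways))
    attr(sets, "provenance") <- "synthetic"
    sets
  })
}

#' Generate a mutation cohort with planted subtypes and survival
#'
#' Each patient is assigned to subtype A with probability
#' `subtype_proportion`. Gene mutations are independent Bernoulli draws at
#' the baseline rate, multiplied by `enrichment_factor` for
#' informative-pathway genes in subtype-A patients (the first
#' `n_informative_pathways` sets). With `balance_burden = TRUE` (default)
#' the background rate of subtype-A patients is lowered so both subtypes
#' have the same expected total mutation count: the planted signal then
#' lives purely in gene identity, not in mutation burden. This matters for
#' the randomized-mutation null model, which preserves per-patient burden by
#' construction — a burden-confounded generator would leave a survival
#' signal that no within-patient permutation can remove. Survival times
#' follow an exponential proportional-hazards model with linear predictor
#' `hazard_log_ratio * 1[subtype A]`; independent uniform censoring is
#' calibrated by bisection to the target censoring rate. Patients with no
#' mutation at all are redrawn, since an empty profile has no propagation
#' seed.
#'
#' @param network A `gene_network` (defines the gene universe).
#' @param pathways Named list of gene sets from [generate_pathways()].
#' @param spec A [synthetic_spec()].
#' @param balance_burden Equalize expected per-sample mutation counts
#'   between subtypes by lowering subtype-A's background rate (default
#'   `TRUE`); requires `enrichment_factor * n_informative_genes < n_genes`.
#'   Set `FALSE` for literal enrichment-only planting, which confounds
#'   subtype with total burden.
#' @return A list of class `synthetic_cohort`: `mutations` (binary matrix),
#'   `clinical` (tibble `sample_id`, `os_months`, `os_event`,
#'   `subtype_true`), `true_labels` (named character vector), and
#'   `informative_pathways`.
#' @export
generate_cohort <- function(network, pathways, spec, balance_burden = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- network$genes
  n_genes <- length(genes)
  rate_hi <- spec$baseline_mutation_rate * spec$enrichment_factor
  if (rate_hi > 1) {
    abort("baseline_mutation_rate * enrichment_factor exceeds 1.",
          class = "metastrat_config_error")
  }
  info_sets <- names(pathways)[seq_len(spec$n_informative_pathways)]
  info_genes <- unique(unlist(pathways[info_sets]))
  info_idx <- match(info_genes, genes)
  info_idx <- info_idx[!is.na(info_idx)]
  n_info <- length(info_idx)
  rate_bg_a <- spec$baseline_mutation_rate
  if (balance_burden) {
    rate_bg_a <- spec$baseline_mutation_rate *
      (n_genes - spec$enrichment_factor * n_info) / (n_genes - n_info)
    if (rate_bg_a < 0) {
      abort(paste("Cannot balance burden:",
                  "enrichment_factor * n_informative_genes >= n_genes."),
            class = "metastrat_config_error")
    }
  }

  with_seed(child_seed(spec$seed, "cohort"), {
    n <- spec$n_samples
    subtype <- ifelse(runif(n) < spec$subtype_proportion, "A", "B")
    base <- rep(spec$baseline_mutation_rate, n_genes)
    rate_a <- rep(rate_bg_a, n_genes)
    rate_a[info_idx] <- rate_hi
    M <- matrix(0, n, n_genes,
                dimnames = list(sprintf("S%04d", seq_len(n)), genes))
    for (s in seq_len(n)) {
      p <- if (subtype[s] == "A") rate_a else base
      row <- rbinom(n_genes, 1, p)
      while (sum(row) == 0) row <- rbinom(n_genes, 1, p)  # need >= 1 seed
      M[s, ] <- row
    }
    lambda0 <- log(2) / spec$median_survival
    lambda <- lambda0 * exp(spec$hazard_log_ratio * (subtype == "A"))
    t_event <- rexp(n, rate = lambda)
    c_max <- calibrate_censoring(lambda, spec$censoring_rate,
                                 mean(subtype == "A"), lambda0,
                                 spec$hazard_log_ratio)
    t_cens <- runif(n, 0, c_max)
    os <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    clinical <- tibble::tibble(
      sample_id = rownames(M),
      os_months = os,
      os_event = event,
      subtype_true = subtype
    )
    structure(list(mutations = M, clinical = clinical,
                   true_labels = setNames(subtype, rownames(M)),
                   informative_pathways = info_sets),
              class = "synthetic_cohort")
  })
}

#' Censoring window achieving a target censored fraction
#'
#' For exponential event times and Uniform(0, c) censoring,
#' P(censored | rate k) = P(C < T) = E[exp(-k C)] = (1 - exp(-k c)) / (k c),
#' decreasing in c; solve the mixture over the two subtype rates for c by
#' bisection.
#' @noRd
calibrate_censoring <- function(lambda, target, prop_a, lambda0, hlr) {
  rates <- c(lambda0, lambda0 * exp(hlr))
  wts <- c(1 - prop_a, prop_a)
  p_cens <- function(cmax) {
    sum(wts * (1 - exp(-rates * cmax)) / (rates * cmax))
  }
  lo <- 1e-6; hi <- 1e6
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (p_cens(mid) > target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Write a synthetic cohort to disk
#'
#' Emits the four standard inputs of the analysis: mutation matrix TSV
#' (samples x genes, 0/1), clinical TSV, edge-list TSV (`gene1`, `gene2`,
#' `score`) and a GMT of the pathway collection.
#'
#' @param cohort A `synthetic_cohort`.
#' @param network The `gene_network` it was generated on.
#' @param pathways The pathway collection.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(cohort, network, pathways, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    mutations = file.path(dir, "mutations.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    edges = file.path(dir, "edges.tsv"),
    gmt = file.path(dir, "pathways.gmt")
  )
  write_matrix_tsv(cohort$mutations, paths[["mutations"]])
  readr::write_tsv(cohort$clinical, paths[["clinical"]])
  readr::write_tsv(network$edges, paths[["edges"]])
  write_gmt(pathways, paths[["gmt"]])
  invisible(paths)
}
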