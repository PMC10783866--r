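# metastrat

Metabolic subtyping of cancer cohorts from somatic mutation profiles alone.

## The problem

Targeted-panel sequencing yields, for each tumor, a short list of mutated
genes — a sparse binary sample × gene matrix. Unlike expression data, such
profiles carry no per-gene quantitative signal, so the standard toolkit for
molecular subtyping (pathway scoring, clustering, survival stratification)
cannot be applied directly. `metastrat` implements a network-smoothing
pipeline that turns binary mutation calls into continuous, expression-like
profiles and derives prognostically distinct metabolic subtypes from them:

1. **Network propagation.** Each patient's mutated genes seed a random walk
   with restart on a protein–protein interaction network (STRING-style
   weighted edges, filtered at combined score > 700). The walk iterates

   `p_{t+1} = (1 − r) W p_t + r p_0`

   with restart probability `r = 0.75` and column-stochastic walk operator
   `W`, until the max-norm change between iterates falls below `1e-6`. The
   stationary distribution `p_∞` is a smoothed mutation profile: mutation
   influence spread over network neighborhoods.
2. **Pathway activity.** Each smoothed profile is scored against a
   collection of metabolic gene sets (GMT) with a single-sample enrichment
   statistic — the integrated running sum over the ranked gene list, with
   rank weight exponent `alpha = 0.25` — giving a sample × pathway activity
   matrix. Singleton gene sets give a gene-level, expression-like profile.
3. **Prognostic screening.** Univariate Cox regression of overall survival
   on each pathway's activity; pathways with Wald `p < 0.05` are retained
   and labelled risk (`HR > 1`) or protective.
4. **Deep clustering.** A structural deep clustering network — an
   autoencoder whose layer representations are delivered into a parallel
   graph-convolution branch over a KNN sample graph, trained with dual
   KL self-supervision — clusters patients on the retained pathways. The
   cluster number `k` is chosen by the average silhouette width over
   `k = 2..10`, and two-cluster labels are oriented so cluster 1 has the
   worse Kaplan–Meier median survival.
5. **Validation.** Kaplan–Meier curves, log-rank tests and Cox models for
   the discovered subtypes, plus a randomized-mutation null model (patient
   bootstrap followed by within-patient permutation preserving per-patient
   mutation counts) to check what survives when gene identity is destroyed.

A seeded synthetic-cohort generator (interaction network, near-disjoint
network-local pathway modules, planted burden-balanced subtypes, and
proportional-hazards survival) makes the whole pipeline testable without
any download.

## Worked example

```r
library(metastrat)

demo <- make_demo("demo", seed = 1)       # writes edges/mutations/clinical/GMT
cfg <- pipeline_config(
  edges     = demo$paths[["edges"]],
  mutations = demo$paths[["mutations"]],
  clinical  = demo$paths[["clinical"]],
  gmt       = demo$paths[["gmt"]],
  out_dir   = "demo/out", seed = 1
)
res <- run_pipeline(cfg)
res
#> <metastrat_result>
#>   training: n = 375, k = 2, 15 prognostic pathways, log-rank p = 2.5e-14
#>   testing:  n = 125, k = 2, log-rank p = 0.127
```

The demo cohort plants two subtypes (log hazard ratio 0.7) that differ only
in *which* pathways their mutations hit, not in how many mutations they
carry. The pipeline retains 15 of 20 pathways as prognostic (7 of the 10
informative ones among them), selects `k = 2` by silhouette, and separates
the training cohort into a poor-prognosis cluster 1 and a better-prognosis
cluster 2 (log-rank `p = 2.5e-14`; subtype hazard ratio for cluster 2 vs
cluster 1 of 0.38). Against the planted labels the training assignment
reaches an adjusted Rand index of 0.92. The 125-patient testing cohort is
re-clustered on the training-derived pathway list and shows the same
two-cluster structure.

Results are tibbles throughout, with `tidy()` / `glance()` methods and
`autoplot()` for Kaplan–Meier curves, silhouette profiles, the
silhouette-vs-k curve and the hazard-ratio forest plot:

```r
glance(res$screen)        # pathway counts by direction
#> # A tibble: 1 × 5
#>   n_pathways n_retained n_risk n_protective alpha
#>        <int>      <int>  <int>        <int> <dbl>
#> 1         20         15      7            8  0.05
autoplot(res$km)          # KM curves of the oriented subtypes
autoplot(res$selection)   # average silhouette across k
```

## Vignette

`vignettes/metastrat-methods.Rmd` documents the model, every tunable
parameter, the synthetic benchmark's design (including what it deliberately
does not emulate), numerical choices, and known limitations — in
particular an analysis of why the screen → cluster → log-rank chain is
anti-conservative on randomized data.
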