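---
title: "Prognostic network modules: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prognostic network modules: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prognet)
```

## The problem

Basal-like breast cancer (BLBC) is an intrinsic molecular subtype with poor
average outcome but marked heterogeneity: some patients relapse early, many
survive long term, and standard clinical variables separate the two groups
poorly. General-purpose prognostic signatures lean heavily on proliferation
and estrogen-receptor biology and therefore score essentially all BLBCs as
high risk. `prognet` implements a subtype-focused alternative: find *network
modules* — sets of genes that are both functionally related (close in a
curated gene–gene interaction network) and co-expressed — whose joint
expression predicts survival, then score patients with a simple index over
those modules.

## The discovery pipeline

1. **Sample QC.** Over a supplied set of housekeeping probes, every pair of
   samples gets a Spearman rank correlation; a sample is kept iff it
   correlates strictly above 0.95 with at least half of the other samples.
   Housekeeping expression should be nearly identical in intact profiles,
   so low rank-correlation flags corrupted or mislabelled arrays.
2. **Variance filter.** The `k = 2500` most variably expressed probes
   (sample variance of log2 intensity; ties broken lexicographically so the
   result is deterministic) enter the survival screen. Variance rather than
   MAD or CV is used because it is the standard microarray filter and has
   no tuning constant.
3. **Univariate Cox screen.** Each probe is fit in a univariate Cox
   proportional-hazards model against disease-free survival. Probes with
   two-sided Wald `p < 0.05` are outcome-associated; hazard ratio above 1
   labels the gene *poor-outcome*, below 1 *good-outcome*.
4. **Network mapping and weighting.** Selected genes are mapped onto a
   functional interaction network; the induced subgraph's edges are
   weighted by the absolute Pearson correlation of the two genes'
   expression. When several probes map to one gene the highest-variance
   probe represents it.
5. **Markov clustering.** MCL alternates expansion (squaring the
   column-stochastic flow matrix) and inflation (entry-wise power followed
   by column renormalisation) until the flow stabilises; clusters are the
   connected components of the limit matrix's support. Self-loops equal to
   each node's maximum incident weight damp the even/odd flow oscillation.
6. **Module filter.** Clusters with at least 8 genes and mean pairwise
   signed Pearson correlation of at least 0.25 (all unordered pairs, not
   just network edges) are kept and numbered 0, 1, … in decreasing size.

## Scoring

The module index of a sample is the difference between the geometric means
of the log2 expression of the poor-outcome genes \(P\) and the good-outcome
genes \(N\):

\[
  I = \Big(\prod_{i \in P} x_i\Big)^{1/n_P} - \Big(\prod_{j \in N} x_j\Big)^{1/n_N}
\]

This is implemented literally on the log2 scale, which requires strictly
positive log2 values; values are validated and the synthetic generator
clips at a floor of 0.5. An `agg = "arithmetic"` option substitutes
arithmetic means for data where positivity cannot be guaranteed. A module
with an empty side contributes 0 for that side, so an all-good-outcome
module scores \(-\mathrm{gm}(N)\). The *combination index* is the
arithmetic mean of all module indices, and cohorts are stratified at the
median combination index (ties at the median go to the low-risk group, a
deterministic convention).

## Survival machinery

The Cox partial likelihood is maximised by Newton–Raphson with Efron's tie
correction by default (Breslow optional); covariates are mean-centered
internally for numerical stability and convergence is declared when the
gradient max-norm falls below `1e-9`. Monotone likelihoods (perfect
separation) are detected by coefficient divergence and flagged
non-converged rather than reported. The Kaplan–Meier estimator, Greenwood
variance, and the Mantel–Haenszel log-rank test are implemented directly;
the Cox score test at \(\beta = 0\) with Breslow ties is included because
it is algebraically identical to the two-group log-rank statistic when
event times are untied, giving the test suite a cross-check between two
independent code paths. P-value scores are \(-\log_{10} p\); base 10 is
conventional for signature comparison and configurable.

## The synthetic world

`synthetic_config()` describes cohorts with *planted* prognostic modules so
that every pipeline stage has ground truth:

* **Rank-1 module model.** Each planted module has a latent activity
  \(f_m \sim N(0,1)\) per sample; member genes are
  \(x = \mu + \lambda f_m + \varepsilon\) with
  \(\lambda = \sigma\sqrt{r/(1-r)}\), which makes the expected pairwise
  within-module Pearson correlation exactly \(r\). This is the simplest
  generator whose modules are simultaneously co-expressed and prognostic —
  precisely what the pipeline assumes.
* **Survival.** Event times are exponential with hazard
  \(h_0\exp(\sum_m \beta_m f_{ms})\); the exponential baseline gives
  closed-form medians for analytic tests. \(h_0 = \log 2 / 60\) per month
  (a 60-month baseline median, a realistic recurrence timescale for
  high-risk breast cancer). Censoring is independent exponential with its
  rate solved numerically so the expected censored fraction matches the
  configured rate.
* **Network.** Erdős–Rényi background (`background_edge_prob = 0.01`, the
  order of density of curated functional-interaction networks) with dense
  planted modules (`module_edge_prob = 0.9`).
* **Defaults** (500 genes, 300 samples, two modules of 12 genes with
  \(|\beta| = 0.8\), \(r = 0.6\), 25% censoring, baseline log2 mean 7,
  noise sd 1) are the standard test world and match cohort sizes typical
  of pooled microarray studies of one breast-cancer subtype.
* **Housekeeping genes** get one tenth the residual noise plus a fixed
  per-probe intensity offset; the offset is what makes inter-sample rank
  correlation over the housekeeping set high for intact samples, so the QC
  filter is genuinely exercisable.
* **IHC generator.** Three cores × three markers (JUN up, CD8/CD20 down)
  per sample, coupled to a standard-normal latent risk; per-core latents
  are binned into valid Allred totals (both components zero or both
  positive).

What the generator does **not** emulate: probe-level microarray artefacts,
heavy-tailed noise, correlated censoring, realistic batch structure beyond
additive offsets, or biologically structured networks (hubs, scale-free
degree). A green end-to-end test therefore establishes that the pipeline
recovers the signal class it is designed for, not that it reproduces any
particular published module list.

## Numerical and design choices

* **MCL parameters.** Inflation defaults to 2.0 (the usual
  middle-granularity choice) and is exposed because module granularity
  depends on it; pruning threshold `1e-5`; convergence when the iterate
  changes by less than `1e-8` in max-norm. Reading clusters from connected
  components of the limit's support makes the output a true partition with
  no tie-breaking ambiguity. A consequence worth knowing: a node whose only
  link into a module is a single weak edge is still assigned to that
  module — MCL flow is relative, so pendant nodes follow their only
  neighbour. Recovered modules can therefore carry a few chance-selected
  extra genes.
* **Module coherence.** "Average Pearson correlation" is computed as the
  signed mean over all within-module pairs — the stricter, fully
  reproducible reading; absolute-value averaging is available via
  `corr_method`.
* **Batch alignment.** Full distance-weighted discrimination requires a
  conic-programming solver; since its role here is removal of additive
  inter-dataset shifts, `batch_center()` substitutes per-batch gene-wise
  mean centering (restoring the global gene mean), which preserves
  within-batch gene–gene correlations exactly. The substitution is recorded
  in the output's `method` attribute.
* **Subtyping.** Standardized centroids are per-gene z-scores across the
  reference, averaged per subtype; samples are median-centered over the
  shared intrinsic genes and assigned by highest Spearman correlation,
  with ties broken by subtype name order (warned). No minimum-correlation
  "unassignable" rule is imposed: the argmax is always returned, because
  any threshold would be an invented constant.
* **Enrichment.** The over-representation test is the one-sided
  hypergeometric tail with Benjamini–Hochberg FDR; the universe defaults
  to the genes of the supplied network, matching the selection domain.
* **IHC composite.** `JUN − CD8 − CD20` over per-marker maxima across
  evaluable cores; range \([-16, 8]\). A composite of exactly 0 is
  reported as *indeterminate* rather than silently binned, because the
  stratification rule is defined only by strict inequalities.
* **Degenerate inputs** are rejected with classed conditions
  (`prognet_input_error`, `prognet_format_error`, `prognet_param_error`,
  `prognet_numeric_error`), which the command-line wrapper maps to exit
  codes 2 and 3.

## Limitations

The package validates itself on synthetic cohorts; applying it to real
data requires user-supplied inputs that are deliberately out of scope:
probe–gene mappings, the intrinsic gene list and subtype reference
profiles, the interaction network, and gene-set collections. Raw-array
normalisation (fRMA) and true DWD batch correction are not implemented.
Exact reproduction of any published module list is not attainable in
principle — the upstream clustering plug-in's inflation and pruning
parameters are unpublished — so testing is property-based throughout.
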