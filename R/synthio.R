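# Synthetic cohorts with planted prognostic modules.
#
# Single-factor module model: each planted module m has a latent activity
# f_m ~ N(0,1) per sample; member genes load on it with a loading chosen so
# the expected within-module pairwise Pearson correlation equals the target
# (lambda^2 = r/(1-r) in units of the noise sd). Survival follows a
# proportional-hazards model on the latent activities with an exponential
# baseline, so Kaplan-Meier medians have closed forms for testing.

#' Synthetic cohort configuration
#'
#' Defaults describe the standard test world: 500 genes, 300 samples, two
#' planted prognostic modules of 12 genes (one poor-outcome with hazard
#' log-ratio +0.8 per latent unit, one good-outcome with -0.8),
#' within-module Pearson 0.6, 25% censoring.
#'
#' @param n_genes,n_samples cohort dimensions.
#' @param planted_modules list of `list(size=, direction=, beta=)`;
#'   direction `"poor"` requires `beta > 0`, `"good"` requires `beta < 0`.
#' @param within_module_corr target pairwise Pearson within a module, in \[0,1).
#' @param baseline_log2_mean mean log2 intensity (must exceed `4 * noise_sd`
#'   so the positive floor at 0.5 is essentially never hit).
#' @param noise_sd per-gene residual sd on the log2 scale; must be > 0.
#' @param background_edge_prob,module_edge_prob Bernoulli edge probabilities
#'   for the simulated interaction network, outside and inside modules.
#' @param censoring_rate expected fraction censored, in \[0,1).
#' @param n_housekeeping number of low-variance housekeeping genes
#'   (residual sd `noise_sd / 10`), placed last in the gene list.
#' @param batch_offsets optional numeric vector of additive per-batch shifts;
#'   samples are split into that many contiguous batches.
#' @param baseline_hazard exponential baseline hazard per month; the default
#'   log(2)/60 gives a 60-month median for a baseline patient.
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 500L,
                             n_samples = 300L,
                             planted_modules = list(
                               list(size = 12L, direction = "poor", beta = 0.8),
                               list(size = 12L, direction = "good", beta = -0.8)),
                             within_module_corr = 0.6,
                             baseline_log2_mean = 7.0,
                             noise_sd = 1.0,
                             background_edge_prob = 0.01,
                             module_edge_prob = 0.9,
                             censoring_rate = 0.25,
                             n_housekeeping = 20L,
                             batch_offsets = NULL,
                             baseline_hazard = log(2) / 60,
                             seed = 1L) {
  chk_prob <- function(x, nm, open_top = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 ||
        (if (open_top) x >= 1 else x > 1))
      stop_param(nm, " must be in [0,1", if (open_top) ")" else "]")
  }
  if (n_genes < 1 || n_samples < 2) stop_param("need n_genes >= 1, n_samples >= 2")
  if (noise_sd <= 0) stop_param("noise_sd must be > 0")
  if (baseline_log2_mean < 4 * noise_sd)
    stop_param("baseline_log2_mean must be >= 4 * noise_sd to keep log2 values positive")
  chk_prob(within_module_corr, "within_module_corr", open_top = TRUE)
  chk_prob(background_edge_prob, "background_edge_prob")
  chk_prob(module_edge_prob, "module_edge_prob")
  chk_prob(censoring_rate, "censoring_rate", open_top = TRUE)
  sizes <- vapply(planted_modules, function(m) as.integer(m$size), 1L)
  if (any(sizes < 1)) stop_param("module sizes must be >= 1")
  if (sum(sizes) > n_genes) stop_param("sum of module sizes exceeds n_genes")
  if (sum(sizes) + n_housekeeping > n_genes)
    stop_param("modules plus housekeeping exceed n_genes")
  for (m in planted_modules) {
    if (!m$direction %in% c("good", "poor")) stop_param("direction must be good/poor")
    if (m$direction == "poor" && m$beta <= 0) stop_param("poor module needs beta > 0")
    if (m$direction == "good" && m$beta >= 0) stop_param("good module needs beta < 0")
  }
  if (baseline_hazard <= 0) stop_param("baseline_hazard must be > 0")
  structure(list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
                 planted_modules = planted_modules,
                 within_module_corr = within_module_corr,
                 baseline_log2_mean = baseline_log2_mean, noise_sd = noise_sd,
                 background_edge_prob = background_edge_prob,
                 module_edge_prob = module_edge_prob,
                 censoring_rate = censoring_rate,
                 n_housekeeping = as.integer(n_housekeeping),
                 batch_offsets = batch_offsets,
                 baseline_hazard = baseline_hazard,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Ground truth for a synthetic cohort
#'
#' Assigns genes to planted modules (first genes, in config order), marks
#' the housekeeping block (last genes), and draws the latent module
#' activities `f_ms ~ N(0,1)`.
#'
#' @param config `synthetic_config`.
#' @return list of class `ground_truth`: `module_genes` (list of disjoint
#'   gene-id sets), `directions`, `betas`, `activities` (modules x samples),
#'   `housekeeping`, `sample_ids`.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  genes <- gene_ids(config$n_genes)
  sizes <- vapply(config$planted_modules, function(m) as.integer(m$size), 1L)
  starts <- cumsum(c(1L, sizes))
  module_genes <- lapply(seq_along(sizes), function(i)
    genes[starts[i]:(starts[i] + sizes[i] - 1L)])
  hk <- if (config$n_housekeeping > 0)
    genes[(config$n_genes - config$n_housekeeping + 1L):config$n_genes]
  else character(0)
  samples <- sprintf("s%04d", seq_len(config$n_samples))
  set.seed(config$seed)
  M <- length(sizes)
  activities <- matrix(rnorm(M * config$n_samples), nrow = M,
                       ncol = config$n_samples,
                       dimnames = list(NULL, samples))
  structure(list(module_genes = module_genes,
                 directions = vapply(config$planted_modules, `[[`, "", "direction"),
                 betas = vapply(config$planted_modules, `[[`, 1, "beta"),
                 activities = activities,
                 housekeeping = hk,
                 sample_ids = samples),
            class = "ground_truth")
}

#' Simulate the functional interaction network
#'
#' Erdos-Renyi background at `background_edge_prob` with dense planted
#' modules at `module_edge_prob`.
#'
#' @param config `synthetic_config`.
#' @return `interaction_network` on all `n_genes` genes.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  truth_genes <- ground_truth(config)$module_genes
  genes <- gene_ids(config$n_genes)
  module_of <- setNames(rep(NA_integer_, config$n_genes), genes)
  for (m in seq_along(truth_genes)) module_of[truth_genes[[m]]] <- m
  set.seed(config$seed + 1L)
  idx <- which(upper.tri(diag(config$n_genes)), arr.ind = TRUE)
  same <- !is.na(module_of[idx[, 1]]) & !is.na(module_of[idx[, 2]]) &
    module_of[idx[, 1]] == module_of[idx[, 2]]
  p <- ifelse(same, config$module_edge_prob, config$background_edge_prob)
  keep <- runif(nrow(idx)) < p
  interaction_network(cbind(genes[idx[keep, 1]], genes[idx[keep, 2]]),
                      nodes = genes)
}

#' Simulate the log2 expression matrix
#'
#' Module gene: `baseline + lambda * f_m + eps`, with
#' `lambda = noise_sd * sqrt(r / (1 - r))` so the expected within-module
#' pairwise Pearson is `r`. Background gene: `baseline + eps`. Housekeeping
#' gene: `baseline + offset + eps/10`, where the fixed per-probe offset
#' emulates stable probe-specific intensities. Values are clipped at a 0.5 floor (the module
#' index takes geometric means of log2 values, which requires positivity);
#' the clip count is recorded in `attr(, "n_clipped")`.
#'
#' @param config `synthetic_config`.
#' @param truth matching `ground_truth`.
#' @return expression matrix (genes x samples) with attributes `n_clipped`
#'   and, when batches are configured, `batch`.
#' @export
generate_expression <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"), inherits(truth, "ground_truth"))
  set.seed(config$seed + 2L)
  n_g <- config$n_genes; n_s <- config$n_samples
  x <- matrix(rnorm(n_g * n_s, sd = config$noise_sd), n_g, n_s,
              dimnames = list(gene_ids(n_g), truth$sample_ids))
  if (length(truth$housekeeping)) {
    # stable probe-specific intensities: housekeeping probes keep a fixed
    # per-probe offset (as real arrays do), so inter-sample rank correlation
    # over the housekeeping set is high for intact samples and the QC filter
    # is meaningfully exercisable
    hk_offset <- rnorm(length(truth$housekeeping), sd = 2)
    x[truth$housekeeping, ] <- x[truth$housekeeping, ] / 10 + hk_offset
  }
  r <- config$within_module_corr
  lambda <- config$noise_sd * sqrt(r / (1 - r))
  for (m in seq_along(truth$module_genes)) {
    g <- truth$module_genes[[m]]
    x[g, ] <- x[g, ] + rep(lambda * truth$activities[m, ], each = length(g))
  }
  x <- x + config$baseline_log2_mean
  if (!is.null(config$batch_offsets)) {
    nb <- length(config$batch_offsets)
    batch <- sort(rep(seq_len(nb), length.out = n_s))
    x <- x + rep(config$batch_offsets[batch], each = n_g)
    attr(x, "batch") <- setNames(batch, truth$sample_ids)
  }
  n_clip <- sum(x < 0.5)
  if (n_clip > 0) x[x < 0.5] <- 0.5
  if (any(x <= 0)) stop_numeric("non-positive expression after clipping")
  attr(x, "n_clipped") <- n_clip
  x
}

#' Simulate survival under a proportional-hazards model
#'
#' Event time `T ~ Exponential(h0 * exp(sum_m beta_m f_ms))`; independent
#' exponential censoring with rate solved numerically so the expected
#' censored fraction equals `censoring_rate`.
#'
#' @param truth `ground_truth`.
#' @param config `synthetic_config`.
#' @return `survival_data`; the uncensored event times are kept in
#'   `attr(, "true_time")`.
#' @export
generate_survival <- function(truth, config) {
  stopifnot(inherits(config, "synthetic_config"), inherits(truth, "ground_truth"))
  set.seed(config$seed + 3L)
  lp <- drop(crossprod(truth$activities, truth$betas))
  h <- config$baseline_hazard * exp(lp)
  n <- config$n_samples
  t_event <- rexp(n, rate = h)
  if (config$censoring_rate > 0) {
    # P(C < T | h_s) = c/(c + h_s) for independent exponentials
    f <- function(cr) mean(cr / (cr + h)) - config$censoring_rate
    cr <- uniroot(f, lower = 1e-12, upper = 1e6, tol = 1e-12)$root
    t_cens <- rexp(n, rate = cr)
  } else {
    t_cens <- rep(Inf, n)
  }
  out <- survival_data(truth$sample_ids, pmin(t_event, t_cens),
                       as.numeric(t_event <= t_cens))
  attr(out, "true_time") <- t_event
  out
}

#' Simulate a 3-marker Allred immunohistochemistry table
#'
#' Three cores per sample for JUN, CD8 and CD20. JUN couples positively and
#' CD8/CD20 negatively to a standard-normal latent risk with strength
#' `risk_link`; a per-core latent is binned into an Allred total in
#' `{0, 2..8}` and decomposed into a consistent (intensity, proportion)
#' pair (both zero or both positive).
#'
#' @param n_samples number of samples.
#' @param risk_link coupling strength (0 = markers independent of risk).
#' @param seed integer seed.
#' @return data.frame (sample, marker, core, intensity, proportion) with the
#'   latent risk in `attr(, "latent_risk")`.
#' @export
generate_ihc <- function(n_samples, risk_link = 1, seed = 1L) {
  if (n_samples < 1) stop_param("n_samples must be >= 1")
  set.seed(seed)
  z <- rnorm(n_samples)
  markers <- c(JUN = 1, CD8 = -1, CD20 = -1)
  totals <- c(0L, 2L, 3L, 4L, 5L, 6L, 7L, 8L)
  rows <- list()
  for (mk in names(markers)) {
    for (core in 1:3) {
      u <- markers[[mk]] * risk_link * z + rnorm(n_samples)
      q <- pnorm(u / sqrt(risk_link^2 + 1))
      tot <- totals[pmin(8L, 1L + floor(q * 8))]
      prop <- ifelse(tot == 0L, 0L, pmin(5L, tot - 1L))
      inten <- tot - prop
      rows[[paste(mk, core)]] <- data.frame(
        sample = sprintf("s%04d", seq_len(n_samples)),
        marker = mk, core = core, intensity = inten, proportion = prop,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "latent_risk") <- z
  out
}

#' Simulate a full cohort
#'
#' Convenience wrapper running every generator off one config.
#'
#' @param config `synthetic_config`.
#' @return list(truth, network, expr, surv) — ground truth, interaction
#'   network, expression matrix, survival table.
#' @export
simulate_cohort <- function(config) {
  truth <- ground_truth(config)
  list(truth = truth,
       network = generate_network(config),
       expr = generate_expression(config, truth),
       surv = generate_survival(truth, config))
}

#' Write a simulated cohort to a directory
#'
#' Emits expression.tsv, survival.tsv, network.tsv and truth.json.
#'
#' @param cohort as from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expr, file.path(dir, "expression.tsv"))
  write_survival(cohort$surv, file.path(dir, "survival.tsv"))
  write_network(cohort$network, file.path(dir, "network.tsv"))
  tr <- cohort$truth
  jsonlite::write_json(
    list(module_genes = tr$module_genes, directions = tr$directions,
         betas = tr$betas, housekeeping = tr$housekeeping),
    file.path(dir, "truth.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
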