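# End-to-end orchestration: discovery (QC -> optional subtype restriction
# -> top-variance probes -> univariate Cox selection -> network mapping ->
# edge weighting -> MCL -> module filtering) and validation (score an
# independent cohort, evaluate every module plus the combination). Every
# output embeds the fully resolved parameter set for provenance.

#' Run module discovery on a cohort
#'
#' @param cohort list with `expr` (probe x sample matrix), `surv`
#'   (`survival_data`), `network` (`interaction_network`), and optionally
#'   `probe_to_gene` (named vector) and `housekeeping` (probe ids for QC).
#' @param alpha univariate Cox selection threshold.
#' @param top_k number of top-variance probes to test (capped at the probe
#'   count).
#' @param min_size,min_corr module filter thresholds.
#' @param inflation MCL inflation.
#' @param qc_threshold,qc_min_fraction housekeeping QC parameters (QC runs
#'   only when `cohort$housekeeping` is supplied).
#' @param out optional path; when given, modules + provenance are written
#'   as JSON.
#' @return list of class `discovery_result`: `modules`, `outcome`,
#'   `weighted_network`, `mcl`, `provenance`.
#' @export
run_discovery <- function(cohort, alpha = 0.05, top_k = 2500L,
                          min_size = 8L, min_corr = 0.25, inflation = 2.0,
                          qc_threshold = 0.95, qc_min_fraction = 0.5,
                          out = NULL) {
  for (nm in c("expr", "surv", "network"))
    if (is.null(cohort[[nm]])) stop_input("discovery: cohort lacks '", nm, "'")
  expr <- cohort$expr
  surv <- as_survival_data(cohort$surv)
  counts <- list(samples_in = ncol(expr), probes_in = nrow(expr))
  if (!is.null(cohort$housekeeping)) {
    qc <- qc_filter_samples(expr, cohort$housekeeping,
                            threshold = qc_threshold,
                            min_fraction = qc_min_fraction)
    expr <- expr[, qc$kept, drop = FALSE]
    surv <- surv[surv$sample %in% qc$kept, , drop = FALSE]
    counts$samples_after_qc <- ncol(expr)
  }
  k <- min(top_k, nrow(expr))
  top <- top_variable_probes(expr, k = k)
  expr_top <- expr[top, , drop = FALSE]
  outcome <- select_outcome_probes(expr_top, surv, alpha = alpha)
  counts$probes_tested <- nrow(outcome)
  counts$probes_selected <- sum(outcome$selected)
  mapped <- map_to_network(outcome, cohort$network,
                           probe_to_gene = cohort$probe_to_gene)
  counts$genes_mapped <- length(mapped$gene_probe)
  wnet <- weight_edges(mapped, expr_top)
  mcl <- mcl_cluster(wnet, inflation = inflation)
  modules <- filter_modules(mcl$clusters, expr_top, outcome,
                            min_size = min_size, min_corr = min_corr,
                            gene_probe = mapped$gene_probe)
  counts$modules <- length(modules)
  prov <- list(parameters = list(alpha = alpha, top_k = k,
                                 min_size = min_size, min_corr = min_corr,
                                 inflation = inflation,
                                 qc_threshold = qc_threshold,
                                 qc_min_fraction = qc_min_fraction),
               counts = counts,
               package_version = as.character(utils::packageVersion("prognet")))
  res <- structure(list(modules = modules, outcome = outcome,
                        weighted_network = wnet, mcl = mcl,
                        provenance = prov),
                   class = "discovery_result")
  if (!is.null(out)) write_modules(res$modules, out, provenance = prov)
  res
}

#' Validate modules on an independent cohort
#'
#' @param modules list of `network_module` (e.g. from [run_discovery()] or
#'   [read_modules()]).
#' @param expr gene x sample matrix of the validation cohort (gene-symbol
#'   rows when modules are gene-based).
#' @param surv `survival_data` for the validation cohort.
#' @param horizon KM horizon in months.
#' @param out optional JSON report path.
#' @return list of class `validation_report`: `scores`
#'   (`risk_score_table`), `per_module` (one [evaluate_module()] result per
#'   module plus `combination`), `table` (summary data.frame shaped like a
#'   per-module HR/p table).
#' @export
run_validation <- function(modules, expr, surv, horizon = 120, out = NULL) {
  surv <- as_survival_data(surv)
  if (!setequal(colnames(expr), surv$sample))
    stop_input("validation: expression and survival samples differ")
  scores <- score_cohort(expr, modules)
  surv <- surv[match(scores$sample, surv$sample), ]
  cols <- setdiff(names(scores), "sample")
  per <- lapply(cols, function(cl)
    evaluate_module(setNames(scores[[cl]], scores$sample), surv,
                    horizon = horizon))
  names(per) <- cols
  tab <- do.call(rbind, lapply(cols, function(cl) {
    ev <- per[[cl]]
    data.frame(module = cl,
               hazard_ratio = ev$cox$coef$hazard_ratio,
               p_value = ev$cox$coef$p_value,
               hr_groups = ev$hr_groups$coef$hazard_ratio,
               logrank_p = ev$logrank$p,
               surv_low = unname(ev$surv_at_horizon["low"]),
               surv_high = unname(ev$surv_at_horizon["high"]),
               stringsAsFactors = FALSE)
  }))
  res <- structure(list(scores = scores, per_module = per, table = tab),
                   class = "validation_report")
  if (!is.null(out))
    jsonlite::write_json(list(table = tab), out, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  res
}

#' Write modules to JSON
#'
#' @param modules list of `network_module`.
#' @param path output path.
#' @param provenance optional provenance list embedded alongside.
#' @export
write_modules <- function(modules, path, provenance = NULL) {
  payload <- list(
    modules = lapply(modules, function(m)
      list(id = m$id, size = m$size, mean_pairwise_r = m$mean_pairwise_r,
           genes = m$genes, direction = as.list(m$direction))))
  if (!is.null(provenance)) payload$provenance <- provenance
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read modules from JSON
#'
#' @param path path written by [write_modules()].
#' @return list of `network_module`.
#' @export
read_modules <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  payload <- jsonlite::read_json(path)
  lapply(payload$modules, function(m)
    structure(list(id = as.integer(m$id),
                   genes = unlist(m$genes, use.names = FALSE),
                   direction = unlist(m$direction),
                   size = as.integer(m$size),
                   mean_pairwise_r = as.numeric(m$mean_pairwise_r)),
              class = "network_module"))
}
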