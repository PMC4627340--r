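# Survival evaluation of module scores: continuous Cox per unit index,
# median-split stratification with log-rank and group-coded Cox hazard
# ratio, Kaplan-Meier per group and the 10-year (120-month) survival
# estimate, signature comparison by P-value score, and clinical covariate
# models.

#' Evaluate one score against survival
#'
#' @param scores named numeric vector (one score per sample; names = sample
#'   ids) or unnamed vector aligned with `surv`.
#' @param surv `survival_data`.
#' @param horizon evaluation horizon in months (default 120 = 10 years).
#' @return list: `cox` (continuous per-unit-index fit), `split` (risk
#'   groups), `logrank`, `hr_groups` (high-vs-low Cox fit), `km_by_group`,
#'   `surv_at_horizon` (per-group S(horizon)), `horizon`.
#' @export
evaluate_module <- function(scores, surv, horizon = 120) {
  if (!is.null(names(scores))) {
    if (!setequal(names(scores), surv$sample))
      stop_input("score samples and survival samples differ")
    scores <- scores[surv$sample]
  } else if (length(scores) != nrow(surv)) {
    stop_input("scores and survival are misaligned")
  }
  cox <- fit_cox(as.numeric(scores), surv)
  split <- median_split(as.numeric(scores))
  lr <- logrank_test(surv, split)
  hr_groups <- fit_cox(as.numeric(split == "high"), surv)
  km <- lapply(levels(split), function(l) kaplan_meier(surv[split == l, ]))
  names(km) <- levels(split)
  s_h <- vapply(levels(split), function(l) {
    k <- km[[l]]
    if (k$max_time < horizon)
      warning("group '", l, "': max follow-up ", round(k$max_time, 1),
              " < horizon ", horizon, "; last KM value carried forward")
    survival_at(k, horizon)
  }, 1)
  list(cox = cox, split = split, logrank = lr, hr_groups = hr_groups,
       km_by_group = km, surv_at_horizon = s_h, horizon = horizon)
}

#' Compare prognostic signatures by P-value score
#'
#' Each signature (a `list(P=, N=)` gene-set pair or a `network_module`)
#' is scored on the cohort, regressed against survival with a continuous
#' Cox model, and summarised by the P-value score (-log10 of the Wald p).
#' Unresolvable signatures (missing genes beyond the 20% rule, degenerate
#' fits) are skipped with a warning.
#'
#' @param expr gene x sample log2 matrix.
#' @param surv `survival_data`.
#' @param signatures named list of signatures.
#' @return data.frame (signature, beta, hazard_ratio, p_value, score)
#'   ranked by descending score.
#' @export
compare_signatures <- function(expr, surv, signatures) {
  if (is.null(names(signatures)) || anyDuplicated(names(signatures)))
    stop_input("signatures must be uniquely named")
  rows <- lapply(names(signatures), function(nm) {
    out <- tryCatch({
      st <- score_cohort(expr, signatures[nm])
      sc <- setNames(st[[nm]], st$sample)
      fit <- fit_cox(as.numeric(sc[surv$sample]), surv)
      if (!fit$converged) stop_numeric("fit did not converge")
      data.frame(signature = nm, beta = fit$coef$beta,
                 hazard_ratio = fit$coef$hazard_ratio,
                 p_value = fit$coef$p_value,
                 score = pvalue_score(fit$coef$p_value),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("signature '", nm, "' skipped: ", conditionMessage(e))
      NULL
    })
    out
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop_input("no signature could be evaluated")
  res[order(-res$score), , drop = FALSE]
}

#' Univariate and multivariate covariate models
#'
#' One univariate Cox fit per clinical covariate and for the score, plus a
#' multivariate fit on a chosen covariate subset (always including the
#' score). Rows with missing covariate values are dropped with a message.
#'
#' @param surv `survival_data` carrying covariate columns.
#' @param scores named numeric vector of per-sample scores.
#' @param covariates character vector of covariate column names.
#' @param multivariate covariates to include alongside the score in the
#'   multivariate fit (default: all of `covariates`).
#' @return list: `univariate` (data.frame term/beta/hazard_ratio/p_value),
#'   `multivariate` (`cox_fit`), `n_used`.
#' @export
covariate_models <- function(surv, scores, covariates,
                             multivariate = covariates) {
  missing_cov <- setdiff(covariates, names(surv))
  if (length(missing_cov)) stop_input("unknown covariate: ", missing_cov[1])
  if (!is.null(names(scores))) scores <- scores[surv$sample]
  X <- cbind(score = as.numeric(scores),
             as.matrix(surv[, covariates, drop = FALSE]))
  ok <- stats::complete.cases(X)
  if (sum(!ok) > 0) message(sum(!ok), " sample(s) dropped for missing covariates")
  Xo <- X[ok, , drop = FALSE]
  so <- surv[ok, , drop = FALSE]
  uni <- do.call(rbind, lapply(colnames(Xo), function(term) {
    fit <- fit_cox(Xo[, term], so)
    data.frame(term = term, beta = fit$coef$beta,
               hazard_ratio = fit$coef$hazard_ratio,
               p_value = fit$coef$p_value, converged = fit$converged,
               stringsAsFactors = FALSE)
  }))
  multi <- fit_cox(Xo[, c("score", multivariate), drop = FALSE], so)
  list(univariate = uni, multivariate = multi, n_used = sum(ok))
}
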