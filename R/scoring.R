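# Module-index scoring. The module index of a sample is the difference
# between the geometric means of the log2 expression of the poor-outcome
# genes (P) and the good-outcome genes (N):
#
#   index = (x_1 x_2 ... x_nP)^(1/nP) - (x_1 x_2 ... x_nN)^(1/nN)
#
# taken literally over log2 values, which must therefore be strictly
# positive. An empty side contributes 0 (a module made only of good-outcome
# genes scores -gm(N)). The combination index is the arithmetic mean of
# the per-module indices.

geom_mean <- function(v) exp(mean(log(v)))

#' Module index for one sample
#'
#' @param sample_expr named numeric vector of strictly positive log2
#'   expression values.
#' @param sets list with character vectors `P` (poor-outcome genes) and `N`
#'   (good-outcome genes); disjoint, at least one non-empty.
#' @param agg `"geometric"` (the literal formula) or `"arithmetic"`
#'   (mean of log2 values, for data where positivity cannot be guaranteed).
#' @return numeric index.
#' @export
module_index <- function(sample_expr, sets, agg = c("geometric", "arithmetic")) {
  agg <- match.arg(agg)
  P <- sets$P; N <- sets$N
  if (length(intersect(P, N)) > 0) stop_input("P and N overlap")
  if (length(P) + length(N) < 1) stop_input("both gene sets empty")
  need <- c(P, N)
  miss <- setdiff(need, names(sample_expr))
  if (length(miss)) stop_input("missing gene value: ", miss[1])
  vals <- sample_expr[need]
  if (agg == "geometric" && any(vals <= 0))
    stop_input("non-positive log2 value for gene ",
               need[which(vals <= 0)[1]], "; geometric mean undefined")
  f <- if (agg == "geometric") geom_mean else mean
  gmP <- if (length(P)) f(sample_expr[P]) else 0
  gmN <- if (length(N)) f(sample_expr[N]) else 0
  gmP - gmN
}

#' Combination index
#'
#' @param indices numeric vector of per-module indices (>= 1).
#' @return arithmetic mean.
#' @export
combination_index <- function(indices) {
  if (length(indices) < 1) stop_input("no indices")
  mean(indices)
}

module_sets <- function(module) {
  list(P = names(module$direction)[module$direction == "poor"],
       N = names(module$direction)[module$direction == "good"])
}

#' Score a cohort against a set of modules
#'
#' Computes each module's index for every sample plus the combination
#' index. Module genes absent from `expr` are dropped with a warning when
#' they are under 20% of the module, otherwise the module is an error.
#'
#' @param expr gene x sample log2 matrix.
#' @param modules list of `network_module` (or of `list(P=, N=)` gene
#'   sets; names used as module labels).
#' @param agg passed to [module_index()].
#' @return data.frame of class `risk_score_table`: sample, one column per
#'   module, `combination`.
#' @export
score_cohort <- function(expr, modules, agg = c("geometric", "arithmetic")) {
  agg <- match.arg(agg)
  if (length(modules) == 0) stop_input("no modules to score")
  labels <- names(modules)
  idx_mat <- matrix(NA_real_, nrow = ncol(expr), ncol = length(modules))
  for (m in seq_along(modules)) {
    mod <- modules[[m]]
    sets <- if (inherits(mod, "network_module")) module_sets(mod) else mod
    if (is.null(labels) || is.na(labels[m]) || labels[m] == "")
      labels[m] <- if (inherits(mod, "network_module"))
        paste0("module_", mod$id) else paste0("module_", m - 1)
    for (side in c("P", "N")) {
      present <- intersect(sets[[side]], rownames(expr))
      n_miss <- length(sets[[side]]) - length(present)
      if (n_miss > 0) {
        if (n_miss > 0.2 * length(c(sets$P, sets$N)))
          stop_input("module '", labels[m], "': ", n_miss,
                     " genes (>20%) missing from expression")
        warning("module '", labels[m], "': dropping ", n_miss,
                " missing gene(s)")
        sets[[side]] <- present
      }
    }
    for (s in seq_len(ncol(expr)))
      idx_mat[s, m] <- module_index(expr[, s], sets, agg = agg)
  }
  out <- data.frame(sample = colnames(expr), idx_mat,
                    stringsAsFactors = FALSE)
  names(out) <- c("sample", labels)
  out$combination <- apply(idx_mat, 1, combination_index)
  class(out) <- c("risk_score_table", "data.frame")
  out
}

#' Median split into high- and low-risk groups
#'
#' Scores strictly above the median are `"high"`; scores at or below it
#' (including all median ties) are `"low"`.
#'
#' @param scores numeric vector (>= 2 values).
#' @return factor with levels `low`, `high`, named by `names(scores)`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop_input("need >= 2 samples to split")
  med <- median(scores)
  if (all(scores == scores[1])) warning("all scores identical; everyone low risk")
  factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
}
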