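# Cohort-level QC and filtering: housekeeping-based sample QC, median
# centering, additive batch alignment (a documented stand-in for DWD),
# and variance-based probe filtering.

#' Housekeeping-correlation sample QC
#'
#' A sample is kept iff its Spearman rank correlation over the housekeeping
#' probes is strictly greater than `threshold` with at least `min_fraction`
#' of the other samples.
#'
#' @param expr probe x sample log2 matrix.
#' @param housekeeping_ids probe ids of the housekeeping set (>= 2 must be
#'   present in `expr`).
#' @param threshold Spearman threshold (strict inequality).
#' @param min_fraction minimum fraction of partner samples above threshold.
#' @return list(kept = sample ids, report = data.frame(sample, fraction,
#'   pass)).
#' @export
qc_filter_samples <- function(expr, housekeeping_ids,
                              threshold = 0.95, min_fraction = 0.5) {
  hk <- intersect(housekeeping_ids, rownames(expr))
  if (length(hk) < 2) stop_input("fewer than 2 housekeeping probes found")
  if (ncol(expr) < 2) stop_input("need at least 2 samples")
  cm <- cor(expr[hk, , drop = FALSE], method = "spearman")
  diag(cm) <- NA
  frac <- rowMeans(cm > threshold, na.rm = TRUE)
  pass <- frac >= min_fraction
  list(kept = colnames(expr)[pass],
       report = data.frame(sample = colnames(expr), fraction = unname(frac),
                           pass = unname(pass), stringsAsFactors = FALSE))
}

#' Median-center an expression matrix
#'
#' @param expr probe x sample matrix.
#' @param axis `"genes"` (each row gets median 0) or `"samples"` (each
#'   column).
#' @return centered matrix.
#' @export
median_center <- function(expr, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  if (length(expr) == 0) stop_input("empty matrix")
  if (axis == "genes") expr - apply(expr, 1, median)
  else sweep(expr, 2, apply(expr, 2, median))
}

#' Additive batch centering
#'
#' Per gene and batch, subtracts the batch mean and restores the global
#' gene mean — a simple stand-in for full distance-weighted discrimination
#' that removes additive inter-dataset shifts while preserving within-batch
#' correlation structure exactly.
#'
#' @param expr probe x sample matrix.
#' @param batch_labels one label per sample.
#' @return corrected matrix; `attr(, "method")` records the stand-in.
#' @export
batch_center <- function(expr, batch_labels) {
  if (length(batch_labels) != ncol(expr))
    stop_input("one batch label per sample required")
  batch_labels <- as.character(batch_labels)
  gm <- rowMeans(expr)
  out <- expr
  for (b in unique(batch_labels)) {
    idx <- which(batch_labels == b)
    if (length(idx) == 1) {
      warning("batch '", b, "' has a single sample; left unshifted")
      next
    }
    out[, idx] <- expr[, idx, drop = FALSE] -
      rowMeans(expr[, idx, drop = FALSE]) + gm
  }
  attr(out, "method") <- "per-batch gene-wise mean centering (DWD stand-in)"
  out
}

#' Top variably expressed probes
#'
#' Probes ranked by descending sample variance of log2 expression; ties
#' broken by lexicographic probe id.
#'
#' @param expr probe x sample matrix.
#' @param k number of probes to return.
#' @return character vector of `k` probe ids, in rank order.
#' @export
top_variable_probes <- function(expr, k = 2500L) {
  if (k > nrow(expr)) stop_param("k = ", k, " exceeds ", nrow(expr), " probes")
  if (k < 1) stop_param("k must be >= 1")
  v <- apply(expr, 1, var)
  ord <- order(-v, rownames(expr))
  rownames(expr)[ord][seq_len(k)]
}
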