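# Nearest-centroid molecular subtype assignment: Spearman rank correlation
# of each sample against standardized subtype centroids over an intrinsic
# gene list. The intrinsic list and reference profiles are user inputs;
# tests use a small synthetic reference.

#' Build standardized subtype centroids
#'
#' Reference expression is restricted to the intrinsic genes, each gene is
#' z-scored across reference samples, and the centroid of a subtype is the
#' per-gene mean of the standardized values over its reference samples.
#' Intrinsic genes absent from the reference, or constant across it, are
#' dropped with a message.
#'
#' @param ref_expr gene x sample reference matrix (gene symbols as
#'   rownames).
#' @param ref_labels subtype label per reference sample.
#' @param intrinsic_genes character vector of intrinsic gene symbols.
#' @return object of class `subtype_centroids`: `genes`, `centroids`
#'   (gene x subtype matrix, subtypes in sorted name order).
#' @export
build_centroids <- function(ref_expr, ref_labels, intrinsic_genes) {
  ref_labels <- as.character(ref_labels)
  if (length(ref_labels) != ncol(ref_expr))
    stop_input("one label per reference sample required")
  if (any(table(ref_labels) == 0) || length(unique(ref_labels)) < 2)
    stop_input("need >= 2 subtypes, each with >= 1 reference sample")
  genes <- intersect(intrinsic_genes, rownames(ref_expr))
  n_missing <- length(setdiff(intrinsic_genes, genes))
  if (n_missing > 0)
    message(n_missing, " intrinsic gene(s) absent from reference; dropped")
  if (length(genes) < 2) stop_input("fewer than 2 intrinsic genes in reference")
  m <- ref_expr[genes, , drop = FALSE]
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    message(sum(sds == 0), " constant intrinsic gene(s) dropped")
    m <- m[sds > 0, , drop = FALSE]
    genes <- rownames(m)
    sds <- sds[sds > 0]
  }
  if (length(genes) < 2) stop_input("fewer than 2 usable intrinsic genes")
  z <- (m - rowMeans(m)) / sds
  labs <- sort(unique(ref_labels))
  cen <- vapply(labs, function(l)
    rowMeans(z[, ref_labels == l, drop = FALSE]), numeric(nrow(z)))
  cen <- matrix(cen, nrow = nrow(z), dimnames = list(genes, labs))
  structure(list(genes = genes, centroids = cen), class = "subtype_centroids")
}

#' Nearest-centroid subtype assignment
#'
#' Each sample is median-centered over the shared intrinsic genes and
#' assigned to the centroid with the highest Spearman rank correlation.
#' Ties are broken by subtype name order with a warning.
#'
#' @param expr gene x sample matrix (gene symbols as rownames; collapse
#'   probes with [collapse_to_genes()] first).
#' @param centroids `subtype_centroids`.
#' @return data.frame(sample, subtype) with the full correlation matrix in
#'   `attr(, "correlations")` (samples x subtypes).
#' @export
assign_subtypes <- function(expr, centroids) {
  shared <- intersect(rownames(expr), centroids$genes)
  if (length(shared) < 2) stop_input("fewer than 2 intrinsic genes shared with centroids")
  m <- expr[shared, , drop = FALSE]
  m <- sweep(m, 2, apply(m, 2, median))
  cc <- cor(m, centroids$centroids[shared, , drop = FALSE], method = "spearman")
  best <- apply(cc, 1, function(r) {
    w <- which(r == max(r))
    if (length(w) > 1) warning("subtype correlation tie; first name order used")
    w[1]
  })
  data.frame(sample = colnames(expr),
             subtype = colnames(cc)[best],
             stringsAsFactors = FALSE) -> out
  attr(out, "correlations") <- cc
  out
}
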