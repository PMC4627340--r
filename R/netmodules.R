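# Module discovery: univariate Cox selection of outcome-associated probes,
# mapping onto the functional interaction network, |Pearson| edge weighting,
# Markov clustering of the weighted network, and size/coherence filtering
# into numbered modules with per-gene outcome directions. Pathway
# over-representation is a hypergeometric tail test with BH FDR.

#' Univariate Cox selection of outcome-associated probes
#'
#' One univariate Cox fit per probe; a probe is selected when its two-sided
#' Wald p-value is below `alpha`. Direction is `"poor"` for hazard ratio
#' > 1 and `"good"` otherwise. Probes whose fit fails (constant expression,
#' separation) are reported with `NA` statistics and never selected.
#'
#' @param expr probe x sample log2 matrix, typically already restricted to
#'   the top-variance probes.
#' @param surv `survival_data` covering exactly the samples of `expr`.
#' @param alpha selection threshold on the Wald p-value.
#' @return data.frame of class `outcome_probe_set`: probe, beta, se,
#'   hazard_ratio, p_value, direction, selected, variance.
#' @export
select_outcome_probes <- function(expr, surv, alpha = 0.05) {
  if (!setequal(colnames(expr), surv$sample))
    stop_input("expression samples and survival samples differ")
  surv <- surv[match(colnames(expr), surv$sample), ]
  probes <- rownames(expr)
  res <- lapply(probes, function(pr) {
    fit <- tryCatch(fit_cox(expr[pr, ], surv), error = function(e) NULL)
    if (is.null(fit) || !fit$converged)
      return(c(NA_real_, NA_real_, NA_real_))
    with(fit$coef, c(beta, se, p_value))
  })
  res <- do.call(rbind, res)
  out <- data.frame(probe = probes,
                    beta = res[, 1], se = res[, 2],
                    hazard_ratio = exp(res[, 1]),
                    p_value = res[, 3],
                    direction = ifelse(res[, 1] > 0, "poor", "good"),
                    selected = !is.na(res[, 3]) & res[, 3] < alpha,
                    variance = apply(expr, 1, var),
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  class(out) <- c("outcome_probe_set", "data.frame")
  out
}

#' Map selected probes onto the interaction network
#'
#' Selected probes are translated to gene symbols and the subgraph induced
#' on matching network nodes is returned. When several selected probes map
#' to one gene, the highest-variance probe is retained.
#'
#' @param probes `outcome_probe_set`.
#' @param network `interaction_network`.
#' @param probe_to_gene named character vector probe -> gene; `NULL` means
#'   probe ids already are gene symbols.
#' @return list(subgraph = `interaction_network`, gene_probe = named vector
#'   gene -> retained probe, unmapped = genes absent from the network).
#' @export
map_to_network <- function(probes, network, probe_to_gene = NULL) {
  sel <- probes[probes$selected, , drop = FALSE]
  if (nrow(sel) == 0) stop_input("no selected probes to map")
  if (is.null(probe_to_gene))
    probe_to_gene <- setNames(sel$probe, sel$probe)
  sel <- sel[sel$probe %in% names(probe_to_gene), , drop = FALSE]
  if (nrow(sel) == 0) stop_input("no selected probe is covered by the mapping")
  sel$gene <- probe_to_gene[sel$probe]
  # highest-variance probe per gene
  keep <- vapply(split(seq_len(nrow(sel)), sel$gene), function(idx) {
    if (length(idx) > 1)
      message("gene ", sel$gene[idx[1]], ": ", length(idx),
              " probes, keeping highest variance")
    idx[which.max(sel$variance[idx])]
  }, 1L)
  sel <- sel[keep, , drop = FALSE]
  in_net <- sel$gene %in% network$nodes
  unmapped <- sel$gene[!in_net]
  mapped <- sel$gene[in_net]
  if (length(mapped) == 0)
    stop_input("no selected gene found in the network; examples: ",
               paste(head(unmapped, 5), collapse = ", "))
  e <- network$edges
  keep_e <- e$from %in% mapped & e$to %in% mapped
  sub <- interaction_network(as.matrix(e[keep_e, , drop = FALSE]),
                             nodes = mapped)
  list(subgraph = sub,
       gene_probe = setNames(sel$probe[in_net], mapped),
       unmapped = unmapped)
}

#' Weight network edges by expression correlation
#'
#' Edge weight is the absolute Pearson correlation of the two genes'
#' retained probes across samples. Zero-variance probes give weight 0 with
#' a warning.
#'
#' @param mapped result of [map_to_network()] (or an `interaction_network`
#'   whose node names index `expr` directly).
#' @param expr probe x sample matrix.
#' @return `weighted_network`: list(nodes, edges with a `weight` column).
#' @export
weight_edges <- function(mapped, expr) {
  if (inherits(mapped, "interaction_network"))
    mapped <- list(subgraph = mapped,
                   gene_probe = setNames(mapped$nodes, mapped$nodes))
  if (ncol(expr) < 3) stop_input("need >= 3 samples for edge correlations")
  net <- mapped$subgraph
  gp <- mapped$gene_probe
  missing <- setdiff(net$nodes, names(gp))
  if (length(missing)) stop_input("node without a retained probe: ", missing[1])
  e <- net$edges
  w <- numeric(nrow(e))
  if (nrow(e) > 0) {
    m <- t(expr[gp[net$nodes], , drop = FALSE])
    colnames(m) <- net$nodes
    sds <- apply(m, 2, sd)
    if (any(sds == 0)) warning("zero-variance probe(s); their edges weighted 0")
    for (i in seq_len(nrow(e))) {
      if (sds[e$from[i]] == 0 || sds[e$to[i]] == 0) w[i] <- 0
      else w[i] <- abs(cor(m[, e$from[i]], m[, e$to[i]]))
    }
  }
  structure(list(nodes = net$nodes,
                 edges = cbind(e, weight = w)),
            class = "weighted_network")
}

#' Markov clustering (MCL) of a weighted network
#'
#' Dense-matrix MCL: the weighted adjacency gets self-loops (each node's
#' maximum incident weight; 1 for isolated nodes), columns are normalized
#' to a stochastic matrix, and expansion (matrix power) alternates with
#' inflation (elementwise power then column renormalization) until the
#' iterate stabilises. Entries below `prune_below` are zeroed after each
#' inflation (then columns renormalized). Clusters are the connected
#' components of the support of the limit matrix, so every node lands in
#' exactly one cluster.
#'
#' @param wnet `weighted_network`.
#' @param inflation inflation exponent (granularity knob; > 1).
#' @param expansion matrix-power exponent.
#' @param prune_below magnitude below which entries are zeroed.
#' @param max_iter,tol iteration cap and max-change convergence tolerance.
#' @return list of class `mcl_result`: `clusters` (list of character
#'   vectors), `converged`, `iterations`, `max_colsum_dev` (worst deviation
#'   of any column sum from 1 across all inflation steps).
#' @export
mcl_cluster <- function(wnet, inflation = 2.0, expansion = 2L,
                        prune_below = 1e-5, max_iter = 200L, tol = 1e-8) {
  if (inflation <= 1) stop_param("inflation must be > 1")
  if (expansion < 2) stop_param("expansion must be >= 2")
  nodes <- wnet$nodes
  n <- length(nodes)
  if (n == 0) stop_input("empty network")
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- wnet$edges
  if (nrow(e) > 0) {
    i <- match(e$from, nodes); j <- match(e$to, nodes)
    A[cbind(i, j)] <- e$weight
    A[cbind(j, i)] <- e$weight
  }
  mx <- apply(A, 1, max)
  diag(A) <- ifelse(mx > 0, mx, 1)
  normalize <- function(M) sweep(M, 2, colSums(M), "/")
  M <- normalize(A)
  max_dev <- 0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    M_old <- M
    Mp <- M
    for (k in seq_len(expansion - 1L)) Mp <- Mp %*% M
    Mp <- Mp^inflation
    Mp <- normalize(Mp)
    Mp[Mp < prune_below] <- 0
    # a pruned column could in principle empty out; restore self-flow
    empty <- colSums(Mp) == 0
    if (any(empty)) Mp[cbind(which(empty), which(empty))] <- 1
    Mp <- normalize(Mp)
    max_dev <- max(max_dev, max(abs(colSums(Mp) - 1)))
    M <- Mp
    if (max(abs(M - M_old)) < tol) { converged <- TRUE; break }
  }
  support <- (M > 0) | t(M > 0)
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  clusters <- split(nodes, comp)
  clusters <- clusters[order(-vapply(clusters, length, 1L),
                             vapply(clusters, min, ""))]
  names(clusters) <- NULL
  structure(list(clusters = clusters, converged = converged,
                 iterations = iter, max_colsum_dev = max_dev),
            class = "mcl_result")
}

#' Filter clusters into network modules
#'
#' Keeps clusters with at least `min_size` genes whose mean pairwise signed
#' Pearson correlation (over all unordered within-cluster pairs) is at
#' least `min_corr`. Kept modules are numbered 0, 1, ... in decreasing
#' size (ties by smallest gene id), and each gene carries its outcome
#' direction from the selection stage.
#'
#' @param clusters list of gene-id vectors (e.g. `mcl_cluster()$clusters`).
#' @param expr probe x sample matrix.
#' @param outcome `outcome_probe_set`.
#' @param min_size minimum module size (inclusive).
#' @param min_corr minimum mean pairwise Pearson (inclusive).
#' @param gene_probe optional named vector gene -> probe row of `expr`;
#'   defaults to identity.
#' @param corr_method `"signed_all_pairs"` (default), `"absolute_all_pairs"`
#'   — whether the module-coherence average uses signed or absolute
#'   correlations.
#' @return list of `network_module`: id, genes, direction (named), size,
#'   mean_pairwise_r.
#' @export
filter_modules <- function(clusters, expr, outcome,
                           min_size = 8L, min_corr = 0.25,
                           gene_probe = NULL,
                           corr_method = c("signed_all_pairs",
                                           "absolute_all_pairs")) {
  corr_method <- match.arg(corr_method)
  if (is.null(gene_probe)) {
    g <- unique(unlist(clusters))
    gene_probe <- setNames(g, g)
  }
  dirs <- setNames(outcome$direction, outcome$probe)
  kept <- list()
  for (cl in clusters) {
    if (length(cl) < min_size) next
    m <- t(expr[gene_probe[cl], , drop = FALSE])
    cc <- cor(m)
    if (corr_method == "absolute_all_pairs") cc <- abs(cc)
    mean_r <- mean(cc[upper.tri(cc)])
    if (is.na(mean_r) || mean_r < min_corr) next
    kept[[length(kept) + 1L]] <- list(genes = sort(cl), size = length(cl),
                                      mean_pairwise_r = mean_r)
  }
  if (length(kept) == 0) return(list())
  ord <- order(-vapply(kept, `[[`, 1L, "size"),
               vapply(kept, function(k) k$genes[1], ""))
  kept <- kept[ord]
  lapply(seq_along(kept), function(i) {
    k <- kept[[i]]
    structure(list(id = i - 1L, genes = k$genes,
                   direction = setNames(dirs[gene_probe[k$genes]], k$genes),
                   size = k$size, mean_pairwise_r = k$mean_pairwise_r),
              class = "network_module")
  })
}

#' @export
print.network_module <- function(x, ...) {
  cat("module", x$id, "-", x$size, "genes, mean pairwise r =",
      round(x$mean_pairwise_r, 3), "\n")
  cat("  poor:", sum(x$direction == "poor"),
      " good:", sum(x$direction == "good"), "\n")
  invisible(x)
}

#' Pathway over-representation of a module
#'
#' One-sided hypergeometric tail test `P(X >= overlap)` of the module's
#' genes against each gene set, restricted to a gene universe, with
#' Benjamini-Hochberg FDR across all sets tested.
#'
#' @param module `network_module` (or a character vector of genes).
#' @param sets named list of gene sets (see [read_gmt()]).
#' @param universe character vector of genes; must contain every module
#'   gene.
#' @return data.frame (set, overlap, set_size, universe_size, p_value, fdr)
#'   sorted by ascending p.
#' @export
enrich_module <- function(module, sets, universe) {
  genes <- if (inherits(module, "network_module")) module$genes else module
  if (!all(genes %in% universe))
    stop_input("module gene(s) outside the universe: ",
               paste(head(setdiff(genes, universe), 3), collapse = ", "))
  if (length(sets) == 0) stop_input("no gene sets supplied")
  N <- length(unique(universe))
  n <- length(unique(genes))
  res <- lapply(names(sets), function(nm) {
    K <- length(intersect(sets[[nm]], universe))
    k <- length(intersect(sets[[nm]], genes))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, universe_size = N,
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res[order(res$p_value, res$set), , drop = FALSE]
}
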