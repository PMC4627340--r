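# Shared fixtures and independent oracles used across the suite.

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Exponential survival fixture with a known log hazard ratio per unit x.
make_surv <- function(n, beta = 0, x = rnorm(n), cens_rate = 0,
                      h0 = 0.05) {
  t_ev <- rexp(n, h0 * exp(beta * x))
  t_c <- if (cens_rate > 0) rexp(n, cens_rate) else rep(Inf, n)
  list(x = x,
       surv = survival_data(sprintf("s%04d", seq_len(n)),
                            pmin(t_ev, t_c), as.numeric(t_ev <= t_c)))
}

# Small config used where the full 500-gene world is not needed.
tiny_config <- function(seed = 1, ...) {
  synthetic_config(n_genes = 60L, n_samples = 80L,
                   planted_modules = list(
                     list(size = 8L, direction = "poor", beta = 0.8)),
                   n_housekeeping = 10L, seed = seed, ...)
}

# Brute-force module index: explicit product and n-th root, no shared code
# with module_index().
oracle_module_index <- function(vals, P, N) {
  gm <- function(g) if (length(g) == 0) 0 else prod(vals[g])^(1 / length(g))
  gm(P) - gm(N)
}

# Exact hypergeometric upper tail P(X >= k) by lchoose summation.
oracle_hyper_tail <- function(k, K, N, n) {
  if (K == 0 || n == 0) return(if (k <= 0) 1 else 0)
  if (k > min(K, n)) return(0)
  j <- max(k, max(0, n - (N - K))):min(K, n)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# Unweighted clique-union graph as a weighted_network, for MCL tests.
clique_network <- function(cliques, bridges = NULL) {
  edges <- do.call(rbind, lapply(cliques, function(cl) {
    cmb <- t(combn(cl, 2))
    data.frame(from = cmb[, 1], to = cmb[, 2], weight = 1,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(bridges)) edges <- rbind(edges, bridges)
  structure(list(nodes = sort(unique(c(edges$from, edges$to))),
                 edges = edges),
            class = "weighted_network")
}
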