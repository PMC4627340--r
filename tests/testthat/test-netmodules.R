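planted_cohort <- function(seed = 1, n_genes = 120, n_samples = 300,
                           beta = 0.8, r = 0.6) {
  cfg <- synthetic_config(n_genes = n_genes, n_samples = n_samples,
                          planted_modules = list(
                            list(size = 12, direction = "poor", beta = beta)),
                          within_module_corr = r, censoring_rate = 0.25,
                          n_housekeeping = 0, seed = seed)
  simulate_cohort(cfg)
}

test_that("univariate Cox selection finds planted prognostic genes", {
  coh <- planted_cohort(seed = 41)
  sel <- select_outcome_probes(coh$expr, coh$surv)
  planted <- coh$truth$module_genes[[1]]
  hits <- sel[sel$probe %in% planted, ]
  expect_gte(mean(hits$selected), 0.8)
  expect_true(all(hits$direction[hits$selected] == "poor"))

  # alpha = 0 selects nothing
  sel0 <- select_outcome_probes(coh$expr, coh$surv, alpha = 0)
  expect_equal(sum(sel0$selected), 0)

  # misaligned samples rejected
  bad <- coh$surv
  bad$sample[1] <- "nope"
  expect_error(select_outcome_probes(coh$expr, bad),
               class = "prognet_input_error")
})

test_that("network mapping induces the right subgraph and probe choice", {
  ops <- data.frame(probe = c("pA1", "pA2", "pB", "pC", "pD"),
                    beta = c(1, 1, 1, -1, 1), se = 1, hazard_ratio = exp(1),
                    p_value = c(0.01, 0.01, 0.01, 0.04, 0.2),
                    direction = c("poor", "poor", "poor", "good", "poor"),
                    selected = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                    variance = c(1, 4, 1, 1, 9), stringsAsFactors = FALSE)
  class(ops) <- c("outcome_probe_set", "data.frame")
  net <- interaction_network(rbind(c("A", "B"), c("C", "D"), c("B", "E")))
  map <- c(pA1 = "A", pA2 = "A", pB = "B", pC = "C", pD = "D")
  expect_message(res <- map_to_network(ops, net, map), "highest variance")
  expect_setequal(res$subgraph$nodes, c("A", "B", "C"))
  expect_equal(nrow(res$subgraph$edges), 1)   # only A-B survives induction
  expect_equal(unname(res$gene_probe["A"]), "pA2")  # higher variance wins
  expect_length(res$unmapped, 0)

  # no selected probe in network -> input error
  net2 <- interaction_network(rbind(c("X", "Y")))
  expect_error(map_to_network(ops, net2, map), class = "prognet_input_error")
})

test_that("edge weights are absolute Pearson correlations", {
  set.seed(43)
  v <- rnorm(50)
  expr <- rbind(A = v, B = -v + 7, C = rnorm(50), D = v + rnorm(50))
  colnames(expr) <- sprintf("s%02d", 1:50)
  net <- interaction_network(rbind(c("A", "B"), c("A", "C"), c("A", "D")))
  w <- weight_edges(net, expr)
  wt <- setNames(w$edges$weight, paste(w$edges$from, w$edges$to))
  expect_equal(unname(wt["A B"]), 1)           # negation -> |r| = 1
  expect_lt(unname(wt["A C"]), 0.3)            # independent noise
  expect_gt(unname(wt["A D"]), 0.5)
  expect_true(all(w$edges$weight >= 0 & w$edges$weight <= 1))

  # identical probes weight exactly 1
  expr2 <- rbind(A = v, B = v)
  colnames(expr2) <- sprintf("s%02d", 1:50)
  w2 <- weight_edges(interaction_network(rbind(c("A", "B"))), expr2)
  expect_equal(w2$edges$weight, 1)

  # independent noise at n = 2000 is close to 0
  set.seed(44)
  expr3 <- rbind(A = rnorm(2000), B = rnorm(2000))
  colnames(expr3) <- sprintf("s%04d", 1:2000)
  w3 <- weight_edges(interaction_network(rbind(c("A", "B"))), expr3)
  expect_lt(w3$edges$weight, 0.1)

  expect_error(weight_edges(net, expr[, 1:2]), class = "prognet_input_error")
  # zero-variance probe: weight 0 with a warning
  expr4 <- rbind(A = rep(1, 10), B = rnorm(10))
  colnames(expr4) <- sprintf("s%02d", 1:10)
  expect_warning(w4 <- weight_edges(interaction_network(rbind(c("A", "B"))),
                                    expr4), "zero-variance")
  expect_equal(w4$edges$weight, 0)
})

test_that("MCL recovers clique structure", {
  # two disjoint triangles -> exactly the two triangles
  tri <- clique_network(list(c("a1", "a2", "a3"), c("b1", "b2", "b3")))
  res <- mcl_cluster(tri)
  expect_true(res$converged)
  expect_length(res$clusters, 2)
  expect_setequal(lapply(res$clusters, sort),
                  list(c("a1", "a2", "a3"), c("b1", "b2", "b3")))

  # one clique stays whole
  k6 <- clique_network(list(sprintf("n%d", 1:6)))
  expect_length(mcl_cluster(k6)$clusters, 1)

  # two 6-cliques joined by a weak bridge split at the bridge
  bridged <- clique_network(list(sprintf("a%d", 1:6), sprintf("b%d", 1:6)),
                            bridges = data.frame(from = "a1", to = "b1",
                                                 weight = 0.1))
  res2 <- mcl_cluster(bridged, inflation = 2.0)
  expect_length(res2$clusters, 2)
  expect_setequal(lapply(res2$clusters, sort),
                  list(sprintf("a%d", 1:6), sprintf("b%d", 1:6)))
  expect_lt(res2$max_colsum_dev, 1e-10)
  expect_error(mcl_cluster(bridged, inflation = 1), class = "prognet_param_error")
})

test_that("MCL output is a partition that never crosses components", {
  set.seed(45)
  for (i in 1:10) {
    n <- sample(10:25, 1)
    nodes <- sprintf("v%02d", 1:n)
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.15
    e <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                    weight = runif(sum(keep), 0.1, 1),
                    stringsAsFactors = FALSE)
    wnet <- structure(list(nodes = nodes, edges = e),
                      class = "weighted_network")
    res <- mcl_cluster(wnet)
    members <- unlist(res$clusters)
    expect_setequal(members, nodes)          # covering
    expect_equal(anyDuplicated(members), 0L) # disjoint
    # no cluster spans two connected components of the input graph
    g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                       vertices = nodes)
    comp <- igraph::components(g)$membership
    for (cl in res$clusters)
      expect_length(unique(comp[cl]), 1)
  }
})

test_that("module filter applies size and coherence thresholds and numbering", {
  set.seed(46)
  n_s <- 200
  f1 <- rnorm(n_s); f2 <- rnorm(n_s)
  mk <- function(f, k, r, prefix) {
    lam <- sqrt(r / (1 - r))
    m <- matrix(rnorm(k * n_s), k, n_s) + rep(lam * f, each = k) + 7
    rownames(m) <- sprintf("%s%02d", prefix, 1:k)
    m
  }
  expr <- rbind(mk(f1, 12, 0.6, "a"), mk(f2, 9, 0.6, "b"),
                mk(rnorm(n_s), 7, 0.9, "c"),
                matrix(rnorm(10 * n_s) + 7, 10, n_s,
                       dimnames = list(sprintf("d%02d", 1:10), NULL)))
  colnames(expr) <- sprintf("s%03d", 1:n_s)
  outcome <- data.frame(probe = rownames(expr), beta = 1,
                        direction = "poor", selected = TRUE,
                        stringsAsFactors = FALSE)
  clusters <- list(sprintf("d%02d", 1:10),        # size 10, incoherent
                   sprintf("c%02d", 1:7),         # size 7: too small
                   sprintf("b%02d", 1:9),         # kept
                   sprintf("a%02d", 1:12))        # kept, larger
  mods <- filter_modules(clusters, expr, outcome)
  expect_length(mods, 2)
  expect_equal(mods[[1]]$id, 0L)
  expect_equal(mods[[1]]$size, 12L)               # decreasing size order
  expect_equal(mods[[2]]$size, 9L)
  expect_gte(mods[[1]]$mean_pairwise_r, 0.25)
  # order of the cluster list does not change the result
  mods2 <- filter_modules(rev(clusters), expr, outcome)
  expect_equal(lapply(mods2, `[[`, "genes"), lapply(mods, `[[`, "genes"))
})

test_that("module filter boundary is inclusive at min_corr", {
  # two genes with exactly known correlation via direct construction
  n <- 400
  make_pair_expr <- function(rho) {
    set.seed(47)
    z1 <- rnorm(n); z2 <- rnorm(n)
    x2 <- rho * z1 + sqrt(1 - rho^2) * z2
    m <- rbind(g1 = z1, g2 = x2, g3 = z1 + rnorm(n, sd = 1e-6))
    colnames(m) <- sprintf("s%03d", 1:n)
    m + 10
  }
  expr <- make_pair_expr(0.3)
  cc <- cor(t(expr))
  mean_r <- mean(cc[upper.tri(cc)])
  outcome <- data.frame(probe = rownames(expr), beta = 1, direction = "poor",
                        selected = TRUE, stringsAsFactors = FALSE)
  kept_at <- function(thr) length(filter_modules(list(rownames(expr)), expr,
                                                 outcome, min_size = 3,
                                                 min_corr = thr))
  expect_equal(kept_at(mean_r), 1)          # >= is inclusive
  expect_equal(kept_at(mean_r + 1e-9), 0)
})

test_that("hypergeometric enrichment matches the combinatorial oracle", {
  universe <- sprintf("u%03d", 1:1000)
  mod_genes <- universe[1:10]
  sets <- list(hit = mod_genes, none = universe[900:950])
  res <- enrich_module(mod_genes, sets, universe)
  # module identical to a set of size 10 drawn from 1000
  expect_equal(res$p_value[res$set == "hit"],
               oracle_hyper_tail(10, 10, 1000, 10), tolerance = 1e-12)
  expect_equal(res$p_value[res$set == "none"], 1)

  # zero overlap with every set -> p = 1, FDR = 1
  res0 <- enrich_module(universe[1:5], list(a = universe[500:520],
                                            b = universe[600:650]), universe)
  expect_true(all(res0$p_value == 1) && all(res0$fdr == 1))

  # duplicated set under two names: identical p, BH unchanged on ties
  res2 <- enrich_module(mod_genes,
                        list(s1 = universe[5:30], s2 = universe[5:30]),
                        universe)
  expect_equal(res2$p_value[1], res2$p_value[2])
  expect_equal(res2$fdr[1], res2$fdr[2])

  expect_error(enrich_module(c(mod_genes, "absent"), sets, universe),
               class = "prognet_input_error")
})
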