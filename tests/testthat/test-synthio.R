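test_that("config validation enforces the stated world", {
  expect_error(tiny_config(noise_sd = 0), class = "prognet_param_error")
  expect_error(tiny_config(within_module_corr = 1), class = "prognet_param_error")
  expect_error(synthetic_config(n_genes = 10, planted_modules = list(
    list(size = 11, direction = "poor", beta = 1))),
    class = "prognet_param_error")
  expect_error(synthetic_config(planted_modules = list(
    list(size = 5, direction = "poor", beta = -1))),
    class = "prognet_param_error")
  expect_error(tiny_config(baseline_log2_mean = 1),
               class = "prognet_param_error")
})

test_that("generators are deterministic given the seed", {
  cfg <- tiny_config(seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$expr, b$expr)
  expect_identical(a$surv$time, b$surv$time)
  ih1 <- generate_ihc(50, risk_link = 1, seed = 9)
  ih2 <- generate_ihc(50, risk_link = 1, seed = 9)
  expect_identical(ih1, ih2)
})

test_that("network generator plants cliques and respects edge probabilities", {
  cfg <- synthetic_config(n_genes = 20, n_samples = 10,
                          planted_modules = list(
                            list(size = 5, direction = "poor", beta = 1)),
                          module_edge_prob = 1, background_edge_prob = 0,
                          n_housekeeping = 0, seed = 3)
  net <- generate_network(cfg)
  expect_equal(nrow(net$edges), choose(5, 2))
  expect_length(net$nodes, 20)
  mod_genes <- ground_truth(cfg)$module_genes[[1]]
  expect_setequal(unique(unlist(net$edges[1:2])), mod_genes)

  cfg0 <- synthetic_config(n_genes = 15, n_samples = 10,
                           planted_modules = list(),
                           background_edge_prob = 0, n_housekeeping = 0,
                           seed = 3)
  expect_equal(nrow(generate_network(cfg0)$edges), 0)
})

test_that("within-module correlation is calibrated by the rank-1 loading", {
  cfg <- synthetic_config(n_genes = 30, n_samples = 2000,
                          planted_modules = list(
                            list(size = 10, direction = "poor", beta = 0.5)),
                          within_module_corr = 0.5, n_housekeeping = 0,
                          seed = 5)
  coh <- simulate_cohort(cfg)
  cc <- cor(t(coh$expr[coh$truth$module_genes[[1]], ]))
  mean_r <- mean(cc[upper.tri(cc)])
  expect_gt(mean_r, 0.45)
  expect_lt(mean_r, 0.55)

  # r = 0: module genes independent
  cfg0 <- synthetic_config(n_genes = 30, n_samples = 2000,
                           planted_modules = list(
                             list(size = 10, direction = "poor", beta = 0.5)),
                           within_module_corr = 0, n_housekeeping = 0,
                           seed = 5)
  coh0 <- simulate_cohort(cfg0)
  cc0 <- cor(t(coh0$expr[coh0$truth$module_genes[[1]], ]))
  expect_lt(mean(abs(cc0[upper.tri(cc0)])), 0.05)

  # housekeeping genes have 10x reduced sd
  cfgh <- tiny_config(seed = 8)
  cohh <- simulate_cohort(cfgh)
  hk_sd <- mean(apply(cohh$expr[cohh$truth$housekeeping, ], 1, sd))
  bg <- setdiff(rownames(cohh$expr),
                c(cohh$truth$housekeeping, unlist(cohh$truth$module_genes)))
  bg_sd <- mean(apply(cohh$expr[bg, ], 1, sd))
  expect_lt(hk_sd, bg_sd / 5)
})

test_that("survival generator has exponential structure and calibrated censoring", {
  # null model, no censoring: event rate 1, KM median = ln 2 / h0 within 10%
  cfg <- synthetic_config(n_genes = 5, n_samples = 5000,
                          planted_modules = list(), censoring_rate = 0,
                          n_housekeeping = 0, seed = 17)
  coh <- simulate_cohort(cfg)
  expect_equal(mean(coh$surv$event), 1)
  km <- kaplan_meier(coh$surv)
  med <- km$time[which(km$surv <= 0.5)[1]]
  expect_lt(abs(med - log(2) / cfg$baseline_hazard) / (log(2) / cfg$baseline_hazard),
            0.1)

  # censoring calibration
  cfg3 <- synthetic_config(n_genes = 20, n_samples = 2000,
                           planted_modules = list(
                             list(size = 8, direction = "poor", beta = 0.7)),
                           censoring_rate = 0.3, n_housekeeping = 0, seed = 23)
  coh3 <- simulate_cohort(cfg3)
  cens_frac <- mean(coh3$surv$event == 0)
  expect_gt(cens_frac, 0.25)
  expect_lt(cens_frac, 0.35)

  # Cox on the true latent activity recovers beta
  fit <- fit_cox(coh3$truth$activities[1, ], coh3$surv)
  expect_lt(abs(fit$coef$beta - 0.7), 0.1)
})

test_that("PH structure: latent-activity Cox covers beta in >= 90% of 50 replicates", {
  hits <- 0L
  for (seed in 1:50) {
    cfg <- synthetic_config(n_genes = 12, n_samples = 200,
                            planted_modules = list(
                              list(size = 8, direction = "poor", beta = 0.6)),
                            censoring_rate = 0.25, n_housekeeping = 0,
                            seed = seed)
    coh <- simulate_cohort(cfg)
    fit <- fit_cox(coh$truth$activities[1, ], coh$surv)
    if (abs(fit$coef$beta - 0.6) <= 2 * fit$coef$se) hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})

test_that("IHC generator produces valid Allred tables linked to latent risk", {
  ih <- generate_ihc(400, risk_link = 1.5, seed = 4)
  expect_true(all(ih$intensity %in% 0:3))
  expect_true(all(ih$proportion %in% 0:5))
  expect_true(all((ih$intensity == 0) == (ih$proportion == 0)))
  tab <- score_ihc_table(ih)
  z <- attr(ih, "latent_risk")
  expect_gt(cor(tab$composite, z), 0.3)

  ih0 <- generate_ihc(1000, risk_link = 0, seed = 4)
  tab0 <- score_ihc_table(ih0)
  expect_lt(abs(cor(tab0$composite, attr(ih0, "latent_risk"))), 0.1)
})

test_that("batch offsets shift batches additively and cohorts write to disk", {
  cfg <- tiny_config(seed = 6, batch_offsets = c(0, 2))
  coh <- simulate_cohort(cfg)
  batch <- attr(coh$expr, "batch")
  d <- mean(coh$expr[, batch == 2]) - mean(coh$expr[, batch == 1])
  expect_lt(abs(d - 2), 0.2)

  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir,
    c("expression.tsv", "survival.tsv", "network.tsv", "truth.json")))))
  back <- read_expression(file.path(dir, "expression.tsv"))
  expect_lt(max(abs(back - coh$expr)), 1e-12)
})
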