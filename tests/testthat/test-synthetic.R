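test_that("gene universe conserves genome-wide per-trio class rates exactly", {
  cfg <- sim_config(n_genes = 300, seed = 5)
  u <- build_gene_universe(cfg)
  expect_equal(sum(2 * u$mu_lof), cfg$per_trio_rate[["LoF"]], tolerance = 1e-12)
  expect_equal(sum(2 * (u$mu_dmis + u$mu_tmis)), cfg$per_trio_rate[["mis"]],
               tolerance = 1e-12)
  expect_equal(sum(2 * u$mu_syn), cfg$per_trio_rate[["synonymous"]],
               tolerance = 1e-12)
  # default marginal matches the control cohort: 411 LoF over 3391 trios
  expect_equal(sum(2 * u$mu_lof), 411 / 3391, tolerance = 1e-12)
  # Dmis/Tmis split follows the configured fraction
  expect_equal(u$mu_dmis / (u$mu_dmis + u$mu_tmis),
               rep(cfg$dmis_fraction, 300))

  # single gene absorbs the whole class rate
  one <- build_gene_universe(sim_config(n_genes = 1,
                                        per_trio_rate = c(LoF = 0.1, mis = 0.6,
                                                          synonymous = 0.275),
                                        seed = 1))
  expect_equal(2 * one$mu_syn, 0.275)

  # determinism under seed
  expect_identical(build_gene_universe(cfg), build_gene_universe(cfg))
})

test_that("simulation config survives a YAML round trip with identical output", {
  cfg <- sim_config(n_genes = 120, cohorts = c(ASD = 200, EE = 80),
                    pi = c(ASD = 0.1, EE = 0.05), seed = 17)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg2)
  expect_identical(st1$records, st2$records)
  expect_identical(st1$universe, st2$universe)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(n_genes = 0))
  expect_error(sim_config(control_trios = -1))
  expect_error(sim_config(pi = c(ASD = 1.2, UDD = 0, EE = 0, ID = 0, SCZ = 0)))
  expect_error(sim_config(shared_pool_fraction = 2))
  expect_error(sim_config(pi = c(A = 0.1)), "case cohorts")
})

test_that("risk assignment honours pi, the shared pool, and the gamma prior", {
  # pi = 0 everywhere: no risk genes, all relative risks exactly 1
  cfg0 <- sim_config(n_genes = 100, pi = c(ASD = 0, UDD = 0, EE = 0,
                                           ID = 0, SCZ = 0), seed = 2)
  u0 <- assign_risk_genes(build_gene_universe(cfg0), cfg0)
  expect_true(all(u0$gamma_lof_ASD == 1))
  expect_true(all(!u0$risk_EE))

  # shared_pool_fraction = 1 with equal pi: one common risk set, Jaccard 1
  cfg1 <- sim_config(n_genes = 200, shared_pool_fraction = 1, seed = 3)
  u1 <- assign_risk_genes(build_gene_universe(cfg1), cfg1)
  risk_sets <- lapply(names(cfg1$cohorts), function(d)
    u1$gene[u1[[paste0("risk_", d)]]])
  for (i in 2:5) expect_setequal(risk_sets[[1]], risk_sets[[i]])
  expect_equal(length(risk_sets[[1]]), floor(0.05 * 200))

  # tiny pi triggers the zero-risk warning
  cfgw <- sim_config(n_genes = 10, pi = c(ASD = 0.05, UDD = 0.05, EE = 0.05,
                                          ID = 0.05, SCZ = 0.05), seed = 4)
  expect_warning(assign_risk_genes(build_gene_universe(cfgw), cfgw),
                 "zero risk genes")
})

test_that("pairwise risk-gene overlap matches the hypergeometric expectation", {
  # pool size 100, each disorder draws 50 shared genes from it:
  # E[overlap] = 50 * 50 / 100 = 25, unique parts disjoint
  cfg <- sim_config(n_genes = 2000, cohorts = c(A = 100, B = 100),
                    pi = c(A = 0.05, B = 0.05), shared_pool_fraction = 0.5)
  n_risk <- floor(0.05 * 2000)
  n_shared <- round(0.5 * n_risk)
  exp_overlap <- n_shared^2 / n_risk
  ov <- vapply(1:200, function(s) {
    cfg$seed <- s
    set.seed(s)
    u <- assign_risk_genes(build_gene_universe(cfg, set_seed = FALSE), cfg)
    sum(u$risk_A & u$risk_B)
  }, numeric(1))
  se <- stats::sd(ov) / sqrt(length(ov))
  expect_lt(abs(mean(ov) - exp_overlap), 3 * se)
})

test_that("cohort counts follow the gamma-Poisson model", {
  cfg <- sim_config(n_genes = 500, seed = 6)
  u <- assign_risk_genes(build_gene_universe(cfg), cfg)

  # zero trios: empty record list
  empty <- simulate_cohort(u, "control", 0, cfg)
  expect_equal(nrow(empty$records), 0)
  expect_error(simulate_cohort(u, "XYZ", 10, cfg), "unknown disorder")

  # control at the published scale: synonymous total within 3 Poisson SD of 932
  ctrl <- simulate_cohort(u, "control", 3391, cfg, seed = 7)
  n_syn <- sum(ctrl$records$consequence == "synonymous")
  expect_lt(abs(n_syn - 932), 3 * sqrt(932))

  # one gene, mu 0.01, gamma 20, N = 100: mean LoF count near 2*100*0.01*20
  one_cfg <- sim_config(n_genes = 1, cohorts = c(D = 100), pi = c(D = 1),
                        per_trio_rate = c(LoF = 0.02, mis = 0.02,
                                          synonymous = 0.02),
                        shared_pool_fraction = 0, seed = 1)
  uu <- build_gene_universe(one_cfg)   # mu_lof = 0.01
  uu$risk_D <- TRUE
  uu$gamma_lof_D <- 20
  uu$gamma_dmis_D <- 1
  counts <- vapply(1:1000, function(s) {
    sum(simulate_cohort(uu, "D", 100, one_cfg,
                        seed = s)$records$consequence %in%
          c("stopgain", "stoploss", "splicing", "frameshift"))
  }, numeric(1))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 40), 3 * se)

  # truth ships with every cohort
  expect_named(ctrl$truth, c("gene", "risk", "gamma_lof", "gamma_dmis"))
  expect_true(all(!ctrl$truth$risk))
})

test_that("simulated missense scores round-trip through classification", {
  cfg <- sim_config(n_genes = 200, cohorts = c(ASD = 500),
                    pi = c(ASD = 0.05), seed = 8)
  st <- simulate_study(cfg)
  recs <- st$records
  cls <- classify_dnm(recs$consequence, recs$score, cfg$dmis_threshold)
  cm <- count_matrix(recs, st$trio_counts, cfg$dmis_threshold)
  expect_equal(sum(cm$LoF + cm$Dmis + cm$Tmis + cm$synonymous + cm$other),
               nrow(recs))
  # per-record classes match the generating classes by construction
  mis <- recs$consequence == "missense"
  expect_true(all(cls[mis] %in% c("Dmis", "Tmis")))
  expect_true(all(!is.na(recs$score[mis])))
  expect_true(all(is.na(recs$score[!mis])))
})

test_that("study simulation is byte-identical under one seed", {
  cfg <- sim_config(n_genes = 100, cohorts = c(ASD = 150, EE = 60),
                    pi = c(ASD = 0.05, EE = 0.05), seed = 99)
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg)
  expect_identical(st1$records, st2$records)
  path1 <- withr::local_tempfile()
  path2 <- withr::local_tempfile()
  write_dnm_table(st1$records, path1)
  write_dnm_table(st2$records, path2)
  expect_identical(readLines(path1), readLines(path2))
})

test_that("null simulations give burden odds ratios centred at one", {
  cfg <- sim_config(n_genes = 150, cohorts = c(ASD = 800), control_trios = 800,
                    pi = c(ASD = 0), seed = 1)
  ors <- t(vapply(1:20, function(s) {
    cfg$seed <- s
    st <- simulate_study(cfg)
    bt <- burden_table(count_matrix(st$records, st$trio_counts))
    stats::setNames(bt$or, bt$class)
  }, numeric(4)))
  for (cl in colnames(ors)) {
    se <- stats::sd(ors[, cl]) / sqrt(nrow(ors))
    expect_lt(abs(mean(ors[, cl]) - 1), 3 * se)
  }
})

test_that("expression simulator plants recoverable modules", {
  # zero noise: within-module correlation exactly 1 in absolute value
  ex0 <- simulate_expression(10, 12, k_modules = 2, noise_sd = 0, seed = 10)
  cm <- abs(stats::cor(t(ex0$expr)))
  same <- outer(ex0$modules$module, ex0$modules$module, "==")
  expect_equal(cm[same], rep(1, sum(same)), tolerance = 1e-12)

  # mirrored 2-module design at noise 0.2: edges at |R| > 0.8 stay within
  ex <- simulate_expression(40, 50, k_modules = 2, noise_sd = 0.2, seed = 11)
  edges <- coexpression_edges(ex$expr, 0.8)
  mod <- stats::setNames(ex$modules$module, ex$modules$gene)
  within <- mod[edges$gene_a] == mod[edges$gene_b]
  expect_gt(nrow(edges), 10)
  expect_gt(mean(within), 0.9)

  expect_identical(simulate_expression(15, 8, seed = 3)$expr,
                   simulate_expression(15, 8, seed = 3)$expr)
  expect_error(simulate_expression(3, 10, k_modules = 5), "more modules")
})

test_that("PPI simulator respects block densities and basic graph sanity", {
  genes <- sprintf("G%05d", 1:150)
  modules <- data.frame(gene = genes, module = rep(c("M1", "M2", "M3"), each = 50))

  none <- simulate_ppi(genes, modules, p_within = 0, p_between = 0, seed = 1)
  expect_equal(nrow(none), 0)

  m <- 20
  full <- simulate_ppi(genes[1:m], modules[1:m, ], p_within = 1,
                       p_between = 0, seed = 2)
  expect_equal(nrow(full), m * (m - 1) / 2)
  expect_true(all(full$gene_a != full$gene_b))
  expect_false(any(duplicated(paste(full$gene_a, full$gene_b))))

  ppi <- simulate_ppi(genes, modules, p_within = 0.3, p_between = 0.02, seed = 3)
  mod <- stats::setNames(modules$module, modules$gene)
  same <- mod[ppi$gene_a] == mod[ppi$gene_b]
  n_within_pairs <- 3 * 50 * 49 / 2
  n_between_pairs <- 150 * 149 / 2 - n_within_pairs
  d_within <- sum(same) / n_within_pairs
  d_between <- sum(!same) / n_between_pairs
  expect_lt(abs(d_within - 0.3), 3 * sqrt(0.3 * 0.7 / n_within_pairs))
  expect_lt(abs(d_between - 0.02), 3 * sqrt(0.02 * 0.98 / n_between_pairs))
  expect_true(all(ppi$combined_score >= 150 & ppi$combined_score <= 999))
})
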