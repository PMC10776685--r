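test_that("the generator is exactly reproducible from its seed", {
  cfg <- sim_config(n_genes = 12, shrnas_per_gene = 4, n_cell_lines = 8,
                    n_duplicate_shrnas = 2, seed = 303)
  s1 <- generate_synthetic_screen(cfg)
  s2 <- generate_synthetic_screen(cfg)
  expect_identical(s1$screen$logfc, s2$screen$logfc)
  expect_identical(s1$mutations, s2$mutations)
  expect_identical(s1$truth, s2$truth)
  # and it does not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); generate_synthetic_screen(cfg); b <- runif(1)
  expect_identical(a, b)
})

test_that("a degenerate configuration yields pure gene effects", {
  cfg <- sim_config(n_genes = 6, shrnas_per_gene = 3, n_cell_lines = 4,
                    pool_offsets = c(poolA = 0), stability_slope = 0,
                    cellline_sd = 0, residual_sd = 0, driver_fraction = 0,
                    frac_logfc_missing = 0, frac_abundance_missing = 0,
                    seed = 304)
  sim <- generate_synthetic_screen(cfg)
  ge <- sim$truth$gene_effects[sim$screen$annotations$gene]
  expect_equal(unname(sim$screen$logfc),
               matrix(unname(ge), nrow = 18, ncol = 4), tolerance = 1e-12)
})

test_that("generator marginal moments match the configuration", {
  cfg <- sim_config(n_genes = 100, shrnas_per_gene = 10, n_cell_lines = 10,
                    driver_fraction = 0, frac_logfc_missing = 0, seed = 305)
  sim <- generate_synthetic_screen(cfg)
  lf <- sim$screen$logfc[seq_len(1000), ]   # 10^4 draws
  po <- cfg$pool_offsets
  exp_mean <- mean(po) + cfg$stability_slope * cfg$stability_mean
  exp_var <- cfg$gene_effect_sd^2 + cfg$cellline_sd^2 + cfg$residual_sd^2 +
    cfg$stability_slope^2 * cfg$stability_sd^2 +
    mean(po^2) - mean(po)^2
  # clustered draws: gene, cell-line and seed effects are shared across
  # entries, so the MC error of the moments is dominated by the cluster counts
  se_mean <- sqrt(cfg$gene_effect_sd^2 / cfg$n_genes +
                  cfg$cellline_sd^2 / cfg$n_cell_lines +
                  cfg$residual_sd^2 / length(lf))
  se_var <- sqrt(2) * (cfg$gene_effect_sd^2 / sqrt(cfg$n_genes) +
                       cfg$cellline_sd^2 / sqrt(cfg$n_cell_lines) +
                       cfg$residual_sd^2 / sqrt(length(lf)))
  expect_lt(abs(mean(lf) - exp_mean), 3 * se_mean + 0.02)
  expect_lt(abs(var(c(lf)) - exp_var), 3 * se_var + 0.05)
  # abundance NB mean
  ab <- sim$screen$annotations$initial_abundance
  expect_lt(abs(mean(ab, na.rm = TRUE) - cfg$abundance_mu),
            3 * cfg$abundance_mu / sqrt(sum(!is.na(ab))) * 2)
})

test_that("batch-removal recovers the injected pool offsets and slope", {
  cfg <- sim_config(n_genes = 50, shrnas_per_gene = 8, n_cell_lines = 2,
                    pool_offsets = c(pA = 1, pB = -1),
                    stability_slope = 0.3, residual_sd = 0.3,
                    driver_fraction = 0, frac_logfc_missing = 0,
                    frac_seed_unstable_missing = 0, seed = 306)
  sim <- generate_synthetic_screen(cfg)
  sc <- collapse_duplicate_measurements(sim$screen)
  cm <- remove_batch_effects(sc, sim$stability)
  stab <- unname(sim$stability$stability[sc$annotations$seed])
  stab[is.na(stab)] <- mean(sim$stability$stability)   # same imputation rule
  for (j in 1:2) {
    removed <- sc$logfc[, j] - cm$values[, j]   # delta_pool + gamma*(stab-c)
    est <- lm(removed ~ pool + I(stab - mean(stab)),
              data = data.frame(removed = removed, pool = sc$annotations$pool,
                                stab = stab))
    offA <- coef(est)[1]
    gam <- coef(est)[3]
    expect_lt(abs(offA - 1) / 1, 0.05)          # pool A offset within 5%
    expect_lt(abs(gam - 0.3) / 0.3, 0.05)       # stability slope within 5%
  }
})

test_that("type-I protocol: seeding, alpha = 0, and skip behaviour", {
  sim <- generate_synthetic_screen(sim_config(
    n_genes = 10, shrnas_per_gene = 6, n_cell_lines = 14,
    background_missense_rate = 0.35, seed = 307))
  b <- nbdep_pipeline(sim$screen, sim$stability, sim$mutations,
                      sim$copy_number)
  genes <- unique(b$screen$annotations$gene)[1:2]
  r1 <- simulate_type1(b, genes = genes, n_datasets = 20, seed = 9)
  r2 <- simulate_type1(b, genes = genes, n_datasets = 20, seed = 9)
  expect_identical(r1$settings, r2$settings)
  expect_equal(r1$overall$n_datasets, 20)
  r0 <- simulate_type1(b, genes = genes, n_datasets = 10, alpha = 0, seed = 9)
  expect_equal(r0$overall$n_rejected, 0L)
})

test_that("MC standard error shrinks like one over root n", {
  sim <- generate_synthetic_screen(sim_config(
    n_genes = 8, shrnas_per_gene = 6, n_cell_lines = 14,
    background_missense_rate = 0.35, seed = 308))
  b <- nbdep_pipeline(sim$screen, sim$stability, sim$mutations, sim$copy_number)
  g <- unique(b$screen$annotations$gene)[1]
  rA <- simulate_type1(b, genes = g, n_datasets = 100, alpha = 0.3, seed = 10)
  rB <- simulate_type1(b, genes = g, n_datasets = 200, alpha = 0.3, seed = 10)
  ratio <- rB$overall$mc_se / rA$overall$mc_se
  expect_lt(abs(ratio - 1 / sqrt(2)), 0.25)
})

test_that("power protocol: reproducible, and a null effect stays near alpha", {
  sim <- generate_synthetic_screen(sim_config(
    n_genes = 10, shrnas_per_gene = 6, n_cell_lines = 20,
    driver_fraction = 0, background_missense_rate = 0.4, seed = 309))
  b <- nbdep_pipeline(sim$screen, sim$stability, sim$mutations, sim$copy_number)
  g <- unique(b$screen$annotations$gene)[1]
  p1 <- simulate_power(b, genes = g, n_m_range = 3, q_values = 1,
                       n_datasets = 60, seed = 11)
  p2 <- simulate_power(b, genes = g, n_m_range = 3, q_values = 1,
                       n_datasets = 60, seed = 11)
  expect_identical(p1$settings, p2$settings)
  # no injected effect: rejection stays in the vicinity of alpha
  expect_lt(p1$overall$rejection_fraction, 0.25)
  # requesting more mutant lines than exist skips the setting with a warning
  expect_warning(pk <- simulate_power(b, genes = g, n_m_range = 15,
                                      q_values = 1, n_datasets = 5, seed = 12),
                 "skipped")
  expect_equal(pk$settings$n_datasets, 0L)
})
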