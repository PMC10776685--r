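test_that("batch correction with nothing estimable is the identity", {
  sc <- toy_screen(G = 3, S = 4, L = 4, pools = "poolA")
  st <- seed_stability_table(unique(sc$annotations$seed),
                             rep(-9, length(unique(sc$annotations$seed))))
  expect_warning(expect_warning(cm <- remove_batch_effects(sc, st),
                                "single pool"), "constant")
  expect_identical(cm$values, sc$logfc)
})

test_that("injected pool offsets on a flat baseline are removed exactly", {
  # 1 cell line, 6 shRNAs, two pools with offsets +2 / -2 over baseline 1.5
  ann <- data.frame(shrna_id = sprintf("s%d", 1:6), gene = "G1",
                    pool = rep(c("pA", "pB"), each = 3),
                    seed = "ACGTACG", initial_abundance = 100,
                    stringsAsFactors = FALSE)
  y <- 1.5 + c(rep(2, 3), rep(-2, 3))
  lf <- matrix(y, 6, 1, dimnames = list(ann$shrna_id, "CL1"))
  sc <- screen_dataset(ann, lf)
  st <- seed_stability_table("ACGTACG", -9)
  cm <- suppressWarnings(remove_batch_effects(sc, st))
  expect_equal(unname(cm$values[, 1]), rep(1.5, 6), tolerance = 1e-12)
})

test_that("per-cell-line correction matches limma's removeBatchEffect", {
  skip_if_not_installed("limma")
  set.seed(9)
  sc <- toy_screen(G = 5, S = 6, L = 3, pools = c("pA", "pB", "pC"))
  st <- toy_stability(sc)
  cm <- remove_batch_effects(sc, st)
  stab <- unname(st$stability[sc$annotations$seed])
  for (j in seq_len(ncol(sc$logfc))) {
    y <- sc$logfc[, j]
    stc <- stab - mean(stab)
    ref <- limma::removeBatchEffect(matrix(y, nrow = 1),
                                    batch = sc$annotations$pool,
                                    covariates = stc)
    expect_equal(unname(cm$values[, j]), as.vector(ref), tolerance = 1e-8)
  }
})

test_that("batch correction is idempotent and rank-preserving under shifts", {
  sc <- toy_screen(G = 4, S = 5, L = 6, seed = 4)
  st <- toy_stability(sc)
  cm <- remove_batch_effects(sc, st)
  sc2 <- sc; sc2$logfc <- cm$values
  cm2 <- remove_batch_effects(sc2, st)
  expect_equal(cm2$values, cm$values, tolerance = 1e-8)

  # adding a constant to one cell line leaves that cell line's ranks unchanged
  sc3 <- sc; sc3$logfc[, 2] <- sc3$logfc[, 2] + 7.3
  r1 <- rank_within_cell_line(remove_batch_effects(sc, st))
  r3 <- rank_within_cell_line(remove_batch_effects(sc3, st))
  expect_identical(r1$ranks[, 2], r3$ranks[, 2])
})

test_that("within-cell-line ranks: ascending, contiguous, deterministic ties", {
  m <- cbind(CL1 = c(a = -3.0, b = -1.0, c = 0.5),
             CL2 = c(a = -1.0, b = NA, c = 2.0),
             CL3 = c(a = -1.0, b = -1.0, c = 0))
  rk <- rank_within_cell_line(m)$ranks
  expect_equal(unname(rk[, "CL1"]), c(1L, 2L, 3L))
  expect_equal(unname(rk[, "CL2"]), c(1L, NA, 2L))
  expect_equal(unname(rk[, "CL3"]), c(1L, 2L, 3L))   # tie broken a before b

  # property: observed ranks are exactly 1..n_observed in every cell line
  sim <- generate_synthetic_screen(sim_config(n_genes = 15, shrnas_per_gene = 5,
                                              n_cell_lines = 10, seed = 5))
  cm <- remove_batch_effects(
    collapse_duplicate_measurements(sim$screen), sim$stability)
  rk2 <- rank_within_cell_line(cm)$ranks
  for (j in seq_len(ncol(rk2))) {
    obs <- rk2[!is.na(rk2[, j]), j]
    expect_identical(sort(unname(obs)), seq_along(obs))
  }
})

test_that("consistent-set selection matches a brute-force oracle", {
  # gene with one shRNA keeps it
  m1 <- matrix(c(1, 2, 3, 4), 1, dimnames = list("s1", sprintf("CL%d", 1:4)))
  cs <- select_consistent_shrnas(structure(list(ranks = m1), class = "nbdep_ranks"),
                                 c(s1 = "G1"))
  expect_identical(retained_shrnas(cs, "G1"), "s1")

  # two identical profiles + one reversed: the identical pair is retained
  m3 <- rbind(s1 = c(1, 5, 2, 6), s2 = c(1, 5, 2, 6), s3 = c(6, 2, 5, 1))
  colnames(m3) <- sprintf("CL%d", 1:4)
  cs3 <- select_consistent_shrnas(structure(list(ranks = m3), class = "nbdep_ranks"),
                                  c(s1 = "G1", s2 = "G1", s3 = "G1"))
  expect_setequal(retained_shrnas(cs3, "G1"), c("s1", "s2"))

  # 6 random profiles vs an independent enumeration of the selection rule
  set.seed(31)
  for (rep_i in 1:5) {
    m6 <- matrix(sample(1:60), 6, 10,
                 dimnames = list(sprintf("s%02d", 1:6), sprintf("CL%02d", 1:10)))
    gm <- setNames(rep("G1", 6), rownames(m6))
    cs6 <- select_consistent_shrnas(structure(list(ranks = m6), class = "nbdep_ranks"), gm)
    # oracle: direct correlation of each row with the column means
    mp <- colMeans(m6)
    cors <- apply(m6, 1, function(x) cor(x, mp))
    keep <- rownames(m6)[order(-cors, rownames(m6))][1:ceiling(6 / 2)]
    expect_setequal(retained_shrnas(cs6, "G1"), keep)
  }
})

test_that("selection size is ceiling(n/2) of observed shRNAs", {
  set.seed(12)
  sim <- generate_synthetic_screen(sim_config(n_genes = 12, shrnas_per_gene = 7,
                                              n_cell_lines = 12, seed = 12))
  b <- nbdep_pipeline(sim$screen, sim$stability, sim$mutations, sim$copy_number)
  tab <- table(b$consistent$gene[b$consistent$retained])
  n_obs <- table(b$consistent$gene)
  expect_true(all(tab == ceiling(n_obs[names(tab)] / 2)))
})

test_that("correction brings values closer to the clean gene signal", {
  cfg <- sim_config(n_genes = 20, shrnas_per_gene = 6, n_cell_lines = 10,
                    pool_offsets = c(pA = 2, pB = -2, pC = 0.5),
                    stability_slope = 0.5, residual_sd = 0.3,
                    driver_fraction = 0, frac_logfc_missing = 0, seed = 21)
  sim <- generate_synthetic_screen(cfg)
  sc <- collapse_duplicate_measurements(sim$screen)
  cm <- remove_batch_effects(sc, sim$stability)
  truth <- sim$truth$gene_effects[sc$annotations$gene]
  signal <- outer(unname(truth), unname(sim$truth$cell_effects), "+")
  rho_raw <- cor(c(sc$logfc), c(signal), method = "spearman")
  rho_cor <- cor(c(cm$values), c(signal), method = "spearman")
  expect_gt(rho_cor, rho_raw)
})
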