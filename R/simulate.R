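# Synthetic pooled-screen generator and the Monte Carlo type-I-error and
# statistical-power protocols.
#
# The generator emulates the structure the pipeline assumes:
#   logFC(s, c) = gene_effect(g(s)) + driver_shift * mutant(g(s), c)
#               + pool_offset(pool(s)) + stability_slope * stab(seed(s))
#               + cell_effect(c) + noise,
# with NB-distributed initial abundances (some below the filter threshold
# and some missing, to exercise the filters), mutation and GISTIC tables
# consistent with the mutant assignments, and optional injected violations
# (hypermutated lines, genes without molecular data, replicated readouts)
# whose realised counts are recorded in the returned `truth`.

.local_seed <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

# deterministic per-replicate substreams: the master seed seeds one draw of
# n replicate seeds; each replicate then reseeds with its own value
.derive_seeds <- function(seed, n) {
  restore <- .local_seed(seed)
  on.exit(restore())
  sample.int(2147483646L, n, replace = FALSE)
}

.runif_int <- function(lo, hi) lo + floor(stats::runif(1) * (hi - lo + 1L))

#' Configuration of the synthetic screen generator
#'
#' Defaults describe a desk-scale screen with the structure of a pooled
#' shRNA viability experiment: three pools with small additive offsets, a
#' linear seed-stability off-target trend, per-gene baseline knockdown
#' effects, per-cell-line offsets, and unit residual noise on the logFC
#' scale. Driver genes additionally depress logFC by `driver_effect` in
#' their mutant cell lines.
#'
#' @param n_genes number of genes.
#' @param shrnas_per_gene shRNAs designed per gene.
#' @param n_cell_lines number of cell lines.
#' @param n_cancer_types cell lines are assigned cyclically to this many
#'   types.
#' @param pool_offsets named numeric vector of additive pool batch effects.
#' @param stability_slope slope of logFC on seed thermodynamic stability.
#' @param stability_mean,stability_sd distribution of generated stability
#'   values (arbitrary energy units, negative = more stable pairing).
#' @param gene_effect_sd sd of per-gene baseline effects.
#' @param cellline_sd sd of per-cell-line random offsets.
#' @param residual_sd residual logFC noise sd.
#' @param driver_fraction fraction of genes made drivers.
#' @param driver_effect logFC shift (<= 0) in a driver's mutant lines.
#' @param driver_class alteration class of the drivers (`"missense"`,
#'   `"non_missense"` or `"amplification"`).
#' @param mutant_lines_per_driver mutant cell lines per driver gene
#'   (default: 20% of cell lines, at least 4).
#' @param background_missense_rate per gene x line probability of a
#'   background missense record (gives null genes testable groups).
#' @param background_nonsense_rate per gene x line probability of a
#'   background nonsense record.
#' @param background_silent_rate per gene x line probability of a silent
#'   (unrecognised, flag-free) record.
#' @param cn_amp_rate,cn_del_rate per gene x line probability of a random
#'   GISTIC 2 / -2 call.
#' @param abundance_mu,abundance_theta NB mean/shape of initial abundances.
#' @param frac_abundance_missing fraction of abundances set missing.
#' @param frac_logfc_missing fraction of logFC entries set missing.
#' @param frac_seed_unstable_missing fraction of seeds omitted from the
#'   stability table (exercises mean imputation).
#' @param n_hypermutated injected hypermutated cell lines.
#' @param n_genes_no_molecular injected genes absent from both molecular
#'   tables.
#' @param n_duplicate_shrnas injected shRNAs with a replicated readout row.
#' @param seed mandatory RNG seed.
#' @return list of class `nbdep_sim_config`.
#' @export
sim_config <- function(n_genes = 100, shrnas_per_gene = 10, n_cell_lines = 40,
                       n_cancer_types = 2,
                       pool_offsets = c(poolA = 0.4, poolB = -0.4, BGPD = 0),
                       stability_slope = 0.15,
                       stability_mean = -9, stability_sd = 2,
                       gene_effect_sd = 0.5, cellline_sd = 0.3, residual_sd = 1,
                       driver_fraction = 0.05, driver_effect = -1,
                       driver_class = "missense",
                       mutant_lines_per_driver = NULL,
                       background_missense_rate = 0.1,
                       background_nonsense_rate = 0.01,
                       background_silent_rate = 0.03,
                       cn_amp_rate = 0.01, cn_del_rate = 0.01,
                       abundance_mu = 500, abundance_theta = 2,
                       frac_abundance_missing = 0.02,
                       frac_logfc_missing = 0.02,
                       frac_seed_unstable_missing = 0.02,
                       n_hypermutated = 0, n_genes_no_molecular = 0,
                       n_duplicate_shrnas = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  cfg <- as.list(environment())
  cfg$driver_class <- match.arg(driver_class,
                                c("missense", "non_missense", "amplification"))
  cfg$mutant_lines_per_driver <- mutant_lines_per_driver %||%
    max(4L, round(0.2 * n_cell_lines))
  sds <- c(stability_sd, gene_effect_sd, cellline_sd, residual_sd)
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  if (cfg$driver_effect > 0) stop("driver_effect must be <= 0 (a depletion)")
  if (round(cfg$driver_fraction * n_genes) > 0 &&
      cfg$mutant_lines_per_driver > n_cell_lines)
    stop("more mutant lines per driver than cell lines")
  structure(cfg, class = "nbdep_sim_config")
}

#' Generate a synthetic pooled shRNA screen with molecular annotations
#'
#' @param config [sim_config()] object.
#' @return list of class `nbdep_sim` with elements `screen`, `stability`,
#'   `mutations`, `copy_number`, `cancer_types`, `truth` (driver genes and
#'   their mutant lines, injected-violation identities, generating effects)
#'   and `config`. Byte-identical for identical seeds.
#' @export
generate_synthetic_screen <- function(config) {
  stopifnot(inherits(config, "nbdep_sim_config"))
  cfg <- config
  restore <- .local_seed(cfg$seed)
  on.exit(restore())

  G <- cfg$n_genes; S <- cfg$shrnas_per_gene; L <- cfg$n_cell_lines
  genes <- sprintf("g%04d", seq_len(G))
  lines <- sprintf("cl%03d", seq_len(L))
  n_sh <- G * S
  shrna <- sprintf("sh%05d", seq_len(n_sh))
  gene_of <- rep(genes, each = S)
  pool <- sample(names(cfg$pool_offsets), n_sh, replace = TRUE)
  seeds7 <- apply(matrix(sample(c("A", "C", "G", "T"), 7L * n_sh, replace = TRUE),
                         nrow = n_sh), 1, paste0, collapse = "")
  useeds <- unique(seeds7)
  stab_val <- stats::setNames(stats::rnorm(length(useeds), cfg$stability_mean,
                                           cfg$stability_sd), useeds)
  # a fraction of seeds is absent from the supplied stability table
  n_drop <- floor(cfg$frac_seed_unstable_missing * length(useeds))
  dropped <- if (n_drop > 0) sample(useeds, n_drop) else character(0)
  stability <- seed_stability_table(setdiff(useeds, dropped),
                                    stab_val[setdiff(useeds, dropped)])

  # molecular universe
  no_mol <- character(0)
  n_drivers <- round(cfg$driver_fraction * G)
  drivers <- if (n_drivers > 0) sort(sample(genes, n_drivers)) else character(0)
  if (cfg$n_genes_no_molecular > 0) {
    cand <- setdiff(genes, drivers)
    no_mol <- sort(sample(cand, cfg$n_genes_no_molecular))
  }
  mol_genes <- setdiff(genes, no_mol)

  driver_lines <- lapply(drivers, function(g) sort(sample(lines, cfg$mutant_lines_per_driver)))
  names(driver_lines) <- drivers

  # mutation records -------------------------------------------------------
  mut_gene <- character(0); mut_line <- character(0); mut_cls <- character(0)
  add_records <- function(gs, ls, cls) {
    mut_gene <<- c(mut_gene, gs); mut_line <<- c(mut_line, ls)
    mut_cls <<- c(mut_cls, rep(cls, length(gs)))
  }
  bg_genes <- setdiff(mol_genes, drivers)
  for (spec in list(c("Missense_Mutation", cfg$background_missense_rate),
                    c("Nonsense_Mutation", cfg$background_nonsense_rate),
                    c("Silent", cfg$background_silent_rate))) {
    rate <- as.numeric(spec[2])
    if (rate <= 0 || !length(bg_genes)) next
    hit <- which(matrix(stats::runif(length(bg_genes) * L), length(bg_genes)) < rate,
                 arr.ind = TRUE)
    add_records(bg_genes[hit[, 1]], lines[hit[, 2]], spec[1])
  }
  drv_cls_label <- c(missense = "Missense_Mutation",
                     non_missense = "Nonsense_Mutation")[cfg$driver_class]
  for (g in drivers) {
    if (cfg$driver_class %in% c("missense", "non_missense"))
      add_records(rep(g, length(driver_lines[[g]])), driver_lines[[g]],
                  unname(drv_cls_label))
  }
  hyper <- character(0)
  if (cfg$n_hypermutated > 0) {
    hyper <- sort(sample(lines, cfg$n_hypermutated))
    # several records per profiled gene: the burden must clear mean + 3 sd
    # even though the injected outliers themselves inflate the sd (with k
    # outliers among n lines the outlier z-score is capped near
    # sqrt((n-k)(n-1)/(nk)), so keep n_hypermutated small relative to
    # n_cell_lines)
    for (h in hyper) {
      gs <- rep(mol_genes, 3L)
      add_records(gs, rep(h, length(gs)), "Missense_Mutation")
    }
  }
  # every profiled gene needs at least one mutation record to count as
  # covered by mutation data
  seen <- unique(mut_gene)
  orphan <- setdiff(mol_genes, seen)
  if (length(orphan))
    add_records(orphan, sample(lines, length(orphan), replace = TRUE), "Silent")
  mutations <- mutation_table(mut_gene, mut_line, mut_cls)

  # copy-number table -------------------------------------------------------
  cn_g <- rep(mol_genes, times = L)
  cn_l <- rep(lines, each = length(mol_genes))
  cn_v <- integer(length(cn_g))
  ramp <- stats::runif(length(cn_g))
  cn_v[ramp < cfg$cn_amp_rate] <- 2L
  cn_v[ramp >= cfg$cn_amp_rate & ramp < cfg$cn_amp_rate + cfg$cn_del_rate] <- -2L
  if (cfg$driver_class == "amplification" && length(drivers)) {
    key <- paste(cn_g, cn_l, sep = "\r")
    for (g in drivers)
      cn_v[match(paste(g, driver_lines[[g]], sep = "\r"), key)] <- 2L
  }
  copy_number <- copy_number_table(cn_g, cn_l, cn_v)

  types <- cancer_type_map(lines, sprintf("type%02d", ((seq_len(L) - 1L) %%
                                                         cfg$n_cancer_types) + 1L))

  # logFC matrix ------------------------------------------------------------
  ge <- stats::setNames(stats::rnorm(G, 0, cfg$gene_effect_sd), genes)
  ce <- stats::setNames(stats::rnorm(L, 0, cfg$cellline_sd), lines)
  base <- ge[gene_of] + unname(cfg$pool_offsets[pool]) +
    cfg$stability_slope * stab_val[seeds7]
  lf <- matrix(stats::rnorm(n_sh * L, 0, cfg$residual_sd), n_sh, L,
               dimnames = list(shrna, lines))
  lf <- lf + base + rep(ce, each = n_sh)
  for (g in drivers) {
    rows <- which(gene_of == g)
    lf[rows, driver_lines[[g]]] <- lf[rows, driver_lines[[g]]] + cfg$driver_effect
  }
  if (cfg$frac_logfc_missing > 0) {
    nmiss <- floor(cfg$frac_logfc_missing * length(lf))
    if (nmiss > 0) lf[sample(length(lf), nmiss)] <- NA_real_
  }

  # initial abundances ------------------------------------------------------
  ab <- as.numeric(stats::rnbinom(n_sh, mu = cfg$abundance_mu,
                                  size = cfg$abundance_theta))
  if (cfg$frac_abundance_missing > 0) {
    nmiss <- floor(cfg$frac_abundance_missing * n_sh)
    if (nmiss > 0) ab[sample(n_sh, nmiss)] <- NA_real_
  }
  low_ab <- shrna[is.na(ab) | ab < 50]

  ann <- data.frame(shrna_id = shrna, gene = gene_of, pool = pool,
                    seed = seeds7, initial_abundance = ab,
                    stringsAsFactors = FALSE)

  # replicated readout rows (chosen among shRNAs that survive the abundance
  # filter so the collapse count is clean)
  dup_ids <- character(0)
  if (cfg$n_duplicate_shrnas > 0) {
    ok <- setdiff(shrna[!(gene_of %in% no_mol)], low_ab)
    dup_ids <- sort(sample(ok, min(cfg$n_duplicate_shrnas, length(ok))))
    extra <- lf[dup_ids, , drop = FALSE] +
      matrix(stats::rnorm(length(dup_ids) * L, 0, cfg$residual_sd),
             length(dup_ids), L)
    lf <- rbind(lf, extra)
  }
  screen <- screen_dataset(ann, lf, allow_duplicate_rows = length(dup_ids) > 0)

  truth <- list(drivers = drivers, driver_lines = driver_lines,
                driver_class = cfg$driver_class,
                gene_effects = ge, cell_effects = ce,
                pool_offsets = cfg$pool_offsets,
                stability_slope = cfg$stability_slope,
                stability_values = stab_val,
                hypermutated_lines = hyper,
                genes_no_molecular = no_mol,
                low_abundance_shrnas = low_ab,
                duplicated_shrnas = dup_ids)
  structure(list(screen = screen, stability = stability, mutations = mutations,
                 copy_number = copy_number, cancer_types = types,
                 truth = truth, config = cfg),
            class = "nbdep_sim")
}

.sim_report <- function(protocol, settings) {
  n_rej <- sum(settings$n_rejected); n_tot <- sum(settings$n_datasets)
  frac <- if (n_tot > 0) n_rej / n_tot else NA_real_
  structure(list(protocol = protocol, settings = settings,
                 overall = list(n_rejected = n_rej, n_datasets = n_tot,
                                rejection_fraction = frac,
                                mc_se = if (n_tot > 0) sqrt(frac * (1 - frac) / n_tot)
                                        else NA_real_)),
            class = "nbdep_sim_report")
}

#' @export
print.nbdep_sim_report <- function(x, ...) {
  cat("simulation report (", x$protocol, "): ",
      x$overall$n_rejected, "/", x$overall$n_datasets,
      " rejections (fraction ", signif(x$overall$rejection_fraction, 4),
      ", MC se ", signif(x$overall$mc_se, 3), ")\n", sep = "")
  invisible(x)
}

# fit the NB model to one gene's retained ranks over given mutant/control
# cells and return the one-sided p (NA when not estimable)
.replicate_p <- function(bundle, gene, mut_cells, wt_cells, n_quad) {
  a <- .assemble_gene_obs(gene, bundle$ranks, bundle$consistent,
                          mut_cells, wt_cells)
  if (a$n_mut < 2L || a$n_ctrl < 2L) return(NA_real_)
  fit <- tryCatch(fit_nb_glmm(glmm_observations(a$r, a$x, a$cell),
                              n_quad = n_quad),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$se_beta)) return(NA_real_)
  wald_one_sided_p(fit$beta, fit$se_beta)
}

#' Type-I-error protocol: random pseudo-groups under the null
#'
#' For each analysed gene with `m` mutant and `w` wild-type cell lines, each
#' replicate draws `n_m ~ Uniform{2..m}` cell lines from ALL cell lines into
#' a pseudo-mutant group and `n_w ~ Uniform{2..w}` from the remainder into a
#' pseudo-wild-type group; because labels are random the null is true by
#' construction. The full NB test runs per replicate on the gene's retained
#' ranks (precomputed ranks and consistent sets are reused -- denoising does
#' not depend on labels) and the type-I error is the fraction of replicates
#' with uncorrected p below `alpha`. Replicates are distributed evenly
#' across genes, remainder to the first genes.
#'
#' @param bundle `nbdep_bundle` from [nbdep_pipeline].
#' @param genes genes to analyse; default: all genes testable for `class`.
#' @param class alteration class defining each gene's (m, w) group sizes.
#' @param n_datasets total number of replicates (default 5000).
#' @param alpha significance level (default 0.05).
#' @param n_quad quadrature nodes.
#' @param seed master seed; per-replicate seeds derive from it.
#' @return `nbdep_sim_report` with one settings row per gene.
#' @export
simulate_type1 <- function(bundle, genes = NULL, class = "missense",
                           n_datasets = 5000, alpha = 0.05, n_quad = 1L, seed) {
  stopifnot(inherits(bundle, "nbdep_bundle"))
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  cells <- colnames(bundle$screen$logfc)
  if (is.null(genes)) genes <- sort(unique(bundle$screen$annotations$gene))
  sizes <- lapply(genes, function(g)
    build_test_groups(bundle$calls, g, class, cells))
  ok <- vapply(sizes, function(gr)
    length(gr$mutant) >= 2L && length(gr$control) >= 2L, logical(1))
  if (any(!ok))
    warning(sum(!ok), " gene(s) skipped (fewer than 2 mutant or 2 wild-type lines)")
  genes <- genes[ok]; sizes <- sizes[ok]
  if (!length(genes)) stop("no analysable gene")

  per <- rep(n_datasets %/% length(genes), length(genes))
  rem <- n_datasets %% length(genes)
  if (rem > 0) per[seq_len(rem)] <- per[seq_len(rem)] + 1L
  seeds <- .derive_seeds(seed, n_datasets)

  rows <- vector("list", length(genes))
  idx <- 0L
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    m <- length(sizes[[gi]]$mutant); w <- length(sizes[[gi]]$control)
    n_rej <- 0L; n_eff <- 0L
    for (rep_i in seq_len(per[gi])) {
      idx <- idx + 1L
      restore <- .local_seed(seeds[idx])
      p <- NA_real_
      for (try_i in 1:10) {           # redraw if missingness empties a group
        n_m <- .runif_int(2L, m)
        n_w <- .runif_int(2L, w)
        mut <- sample(cells, n_m)
        wt <- sample(setdiff(cells, mut), min(n_w, length(cells) - n_m))
        p <- .replicate_p(bundle, g, mut, wt, n_quad)
        if (!is.na(p)) break
      }
      restore()
      if (!is.na(p)) {
        n_eff <- n_eff + 1L
        if (p < alpha) n_rej <- n_rej + 1L
      }
    }
    frac <- if (n_eff > 0) n_rej / n_eff else NA_real_
    rows[[gi]] <- data.frame(gene = g, n_m = m, n_w = w, q = NA_real_,
                             n_datasets = n_eff, n_rejected = n_rej,
                             rejection_fraction = frac,
                             mc_se = if (n_eff > 0) sqrt(frac * (1 - frac) / n_eff)
                                     else NA_real_,
                             stringsAsFactors = FALSE)
  }
  .sim_report("type1", do.call(rbind, rows))
}

#' Statistical-power protocol: subsampled mutant and wild-type lines
#'
#' For each analysed gene (which must carry a real or injected
#' mutant-depletion effect), each setting subsamples `n_m` of the gene's
#' mutant cell lines and `n_w = q n_m` of its wild-type lines and runs the
#' NB test; the estimated power of a setting is its rejection fraction at
#' uncorrected `alpha`.
#'
#' @inheritParams simulate_type1
#' @param genes genes with a depletion effect to analyse.
#' @param n_m_range mutant group sizes (default `2:10`).
#' @param q_values wild-type/mutant ratios (default `1:4`).
#' @param n_datasets replicates per (gene, n_m, q) setting (default 800).
#' @return `nbdep_sim_report` with one settings row per (gene, n_m, q).
#' @export
simulate_power <- function(bundle, genes, class = "missense",
                           n_m_range = 2:10, q_values = c(1, 2, 3, 4),
                           n_datasets = 800, alpha = 0.05, n_quad = 1L, seed) {
  stopifnot(inherits(bundle, "nbdep_bundle"))
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  cells <- colnames(bundle$screen$logfc)
  grid <- expand.grid(gene = genes, n_m = n_m_range, q = q_values,
                      stringsAsFactors = FALSE)
  seeds <- .derive_seeds(seed, nrow(grid) * n_datasets)
  rows <- vector("list", nrow(grid))
  for (si in seq_len(nrow(grid))) {
    g <- grid$gene[si]; n_m <- grid$n_m[si]; q <- grid$q[si]
    n_w <- q * n_m
    gr <- build_test_groups(bundle$calls, g, class, cells)
    if (length(gr$mutant) < n_m || length(gr$control) < n_w) {
      warning("setting skipped (gene ", g, ", n_m ", n_m, ", q ", q,
              "): insufficient mutant or wild-type lines")
      rows[[si]] <- data.frame(gene = g, n_m = n_m, n_w = n_w, q = q,
                               n_datasets = 0L, n_rejected = 0L,
                               rejection_fraction = NA_real_, mc_se = NA_real_,
                               stringsAsFactors = FALSE)
      next
    }
    n_rej <- 0L; n_eff <- 0L
    for (rep_i in seq_len(n_datasets)) {
      restore <- .local_seed(seeds[(si - 1L) * n_datasets + rep_i])
      p <- NA_real_
      for (try_i in 1:10) {
        mut <- sample(gr$mutant, n_m)
        wt <- sample(gr$control, n_w)
        p <- .replicate_p(bundle, g, mut, wt, n_quad)
        if (!is.na(p)) break
      }
      restore()
      if (!is.na(p)) {
        n_eff <- n_eff + 1L
        if (p < alpha) n_rej <- n_rej + 1L
      }
    }
    frac <- if (n_eff > 0) n_rej / n_eff else NA_real_
    rows[[si]] <- data.frame(gene = g, n_m = n_m, n_w = n_w, q = q,
                             n_datasets = n_eff, n_rejected = n_rej,
                             rejection_fraction = frac,
                             mc_se = if (n_eff > 0) sqrt(frac * (1 - frac) / n_eff)
                                     else NA_real_,
                             stringsAsFactors = FALSE)
  }
  .sim_report("power", do.call(rbind, rows))
}
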