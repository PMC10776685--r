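# Step 4 driver: assemble per-gene observations from the global rank matrix
# and the consistent-shRNA set, fit the NB mixed model per (gene, alteration
# class), adjust within class by Benjamini-Hochberg, and provide pan-cancer,
# cancer-specific and ablation entry points.

.alteration_classes <- c("missense", "non_missense", "amplification")

#' Run preprocessing, denoising, ranking, selection and classification
#'
#' Bundles every label-free stage of the pipeline so that the per-gene tests
#' (and the simulation protocols, which refit only the mixed model) can
#' reuse the products.
#'
#' @param screen [screen_dataset()] (raw; duplicates allowed).
#' @param stability [seed_stability_table()].
#' @param mutations [mutation_table()].
#' @param cn [copy_number_table()].
#' @param cancer_types optional [cancer_type_map()].
#' @param min_abundance abundance filter threshold (default 50).
#' @return object of class `nbdep_bundle` with elements `screen` (filtered),
#'   `corrected`, `ranks`, `consistent`, `calls`, `cancer_types`, `report`.
#' @export
nbdep_pipeline <- function(screen, stability, mutations, cn,
                           cancer_types = NULL, min_abundance = 50) {
  pre <- preprocess_screen(screen, mutations, cn, min_abundance = min_abundance)
  corrected <- remove_batch_effects(pre$screen, stability)
  ranks <- rank_within_cell_line(corrected)
  gene_of <- stats::setNames(pre$screen$annotations$gene,
                             pre$screen$annotations$shrna_id)
  consistent <- select_consistent_shrnas(ranks, gene_of)
  calls <- classify_gene_cell_alterations(mutations, cn)
  structure(list(screen = pre$screen, corrected = corrected, ranks = ranks,
                 consistent = consistent, calls = calls,
                 cancer_types = cancer_types, report = pre$report),
            class = "nbdep_bundle")
}

#' @export
print.nbdep_bundle <- function(x, ...) {
  cat("nbdep pipeline bundle\n")
  print(x$report)
  cat("  retained shRNAs in consistent sets:", sum(x$consistent$retained), "\n")
  invisible(x)
}

# Gather the NB-model observations of one gene over given mutant/control
# cells: ranks of the gene's RETAINED shRNAs, missing entries dropped.
.assemble_gene_obs <- function(gene, ranks, consistent, mutant, control) {
  ids <- retained_shrnas(consistent, gene)
  cells <- c(mutant, control)
  ids <- intersect(ids, rownames(ranks$ranks))
  if (!length(ids) || !length(cells))
    return(list(n_mut = 0L, n_ctrl = 0L, n_shrnas = 0L))
  sub <- ranks$ranks[ids, cells, drop = FALSE]
  obs_idx <- which(!is.na(sub), arr.ind = TRUE)
  if (!nrow(obs_idx)) return(list(n_mut = 0L, n_ctrl = 0L, n_shrnas = 0L))
  cell <- cells[obs_idx[, 2]]
  x <- as.numeric(cell %in% mutant)
  cells_obs <- unique(cell)
  list(r = sub[obs_idx], x = x, cell = cell,
       n_mut = sum(cells_obs %in% mutant),
       n_ctrl = sum(cells_obs %in% control),
       n_shrnas = length(unique(ids[obs_idx[, 1]])))
}

.result_row <- function(gene, cls, n_mut = NA_integer_, n_wt = NA_integer_,
                        n_shrnas = NA_integer_, fit = NULL, p = NA_real_,
                        skipped = "") {
  data.frame(gene = gene, alteration_class = cls,
             n_mutant = as.integer(n_mut), n_wildtype = as.integer(n_wt),
             n_shrnas_used = as.integer(n_shrnas),
             beta = if (is.null(fit)) NA_real_ else fit$beta,
             se_beta = if (is.null(fit)) NA_real_ else fit$se_beta,
             theta = if (is.null(fit)) NA_real_ else fit$theta,
             sigma2 = if (is.null(fit)) NA_real_ else fit$sigma2,
             p_value = p, q_value = NA_real_,
             converged = if (is.null(fit)) NA else fit$converged,
             skipped_reason = skipped, stringsAsFactors = FALSE)
}

#' Test one gene for self-dependency in one alteration class
#'
#' Fits the NB random-intercept model to the viability ranks of the gene's
#' retained shRNAs over the mutant and strictly wild-type cell lines and
#' computes the one-sided Wald p-value for depletion in mutant lines. The
#' combination is testable only when at least two mutant and two wild-type
#' cell lines each contribute at least one observed rank; otherwise the
#' result row is marked skipped with a reason, carrying no estimates.
#'
#' @param gene gene symbol.
#' @param cls alteration class (`"missense"`, `"non_missense"`,
#'   `"amplification"`).
#' @param ranks `nbdep_ranks` object (global within-cell-line ranks).
#' @param consistent `nbdep_consistent` selection table.
#' @param groups `nbdep_test_groups` for this gene and class.
#' @param n_quad quadrature nodes for the NB fit.
#' @return one-row data.frame in the results schema (q_value is filled by
#'   the multi-gene drivers).
#' @export
test_gene <- function(gene, cls, ranks, consistent, groups, n_quad = 1L) {
  stopifnot(inherits(groups, "nbdep_test_groups"))
  if (length(groups$mutant) < 2L)
    return(.result_row(gene, cls, length(groups$mutant), length(groups$control),
                       skipped = "insufficient mutant group"))
  if (length(groups$control) < 2L)
    return(.result_row(gene, cls, length(groups$mutant), length(groups$control),
                       skipped = "insufficient wild-type group"))
  a <- .assemble_gene_obs(gene, ranks, consistent, groups$mutant, groups$control)
  if (a$n_mut < 2L || a$n_ctrl < 2L)
    return(.result_row(gene, cls, a$n_mut, a$n_ctrl, a$n_shrnas,
                       skipped = "insufficient observed ranks"))
  fit <- tryCatch(fit_nb_glmm(glmm_observations(a$r, a$x, a$cell), n_quad = n_quad),
                  error = function(e) e)
  if (inherits(fit, "error"))
    return(.result_row(gene, cls, a$n_mut, a$n_ctrl, a$n_shrnas,
                       skipped = paste0("fit error: ", conditionMessage(fit))))
  p <- if (is.finite(fit$se_beta)) wald_one_sided_p(fit$beta, fit$se_beta) else NA_real_
  .result_row(gene, cls, a$n_mut, a$n_ctrl, a$n_shrnas, fit = fit, p = p)
}

.bh_within <- function(res, strata) {
  ok <- res$skipped_reason == "" & !is.na(res$p_value)
  for (s in unique(strata[ok])) {
    idx <- which(ok & strata == s)
    res$q_value[idx] <- bh_adjust(res$p_value[idx])
  }
  res
}

#' Pan-cancer self-dependency screen
#'
#' Tests every (gene, alteration class) combination over all cell lines of
#' the bundle, then adjusts p-values by Benjamini-Hochberg separately within
#' each alteration class across the tested genes. Output rows are ordered by
#' gene, then class; significance is `q_value < alpha`.
#'
#' @param bundle `nbdep_bundle` from [nbdep_pipeline].
#' @param classes alteration classes to test (default all three).
#' @param alpha significance level used downstream (recorded only; default
#'   0.05).
#' @param n_quad quadrature nodes for the NB fits.
#' @return data.frame in the results schema, one row per gene x class.
#' @export
run_pancancer <- function(bundle, classes = .alteration_classes,
                          alpha = 0.05, n_quad = 1L) {
  stopifnot(inherits(bundle, "nbdep_bundle"))
  classes <- match.arg(classes, .alteration_classes, several.ok = TRUE)
  cells <- colnames(bundle$screen$logfc)
  genes <- sort(unique(bundle$screen$annotations$gene))
  rows <- vector("list", length(genes) * length(classes))
  i <- 0L
  for (g in genes) for (cls in classes) {
    i <- i + 1L
    grp <- build_test_groups(bundle$calls, g, cls, cells)
    rows[[i]] <- test_gene(g, cls, bundle$ranks, bundle$consistent, grp,
                           n_quad = n_quad)
  }
  res <- do.call(rbind, rows)
  if (!any(res$skipped_reason == "")) warning("no testable (gene, class) combination")
  res <- .bh_within(res, res$alteration_class)
  res[order(res$gene, res$alteration_class, method = "radix"), , drop = FALSE]
}

#' Cancer-type-specific self-dependency screens
#'
#' Restricts the bundle to each cancer type with at least `min_lines` cell
#' lines (evaluated after preprocessing), tests genes with at least two
#' mutant and two wild-type lines within the type, and adjusts by
#' Benjamini-Hochberg within each (type, class) stratum.
#'
#' @inheritParams run_pancancer
#' @param types [cancer_type_map()]; defaults to the bundle's map.
#' @param min_lines minimum cell lines per analysed cancer type (default 4).
#' @return data.frame in the results schema with a leading `cancer_type`
#'   column.
#' @export
run_cancer_specific <- function(bundle, types = NULL, min_lines = 4,
                                classes = .alteration_classes,
                                alpha = 0.05, n_quad = 1L) {
  stopifnot(inherits(bundle, "nbdep_bundle"))
  types <- types %||% bundle$cancer_types
  if (is.null(types)) stop("no cancer-type map supplied")
  classes <- match.arg(classes, .alteration_classes, several.ok = TRUE)
  cells <- colnames(bundle$screen$logfc)
  type_of <- types$type_of[cells]
  keep_types <- names(which(table(type_of) >= min_lines))
  if (!length(keep_types)) {
    warning("no cancer type has at least ", min_lines, " cell lines")
    return(cbind(cancer_type = character(0),
                 .result_row(character(0), character(0))[0, , drop = FALSE]))
  }
  genes <- sort(unique(bundle$screen$annotations$gene))
  out <- list()
  for (ty in sort(keep_types)) {
    ty_cells <- cells[!is.na(type_of) & type_of == ty]
    rows <- list()
    i <- 0L
    for (g in genes) for (cls in classes) {
      i <- i + 1L
      grp <- build_test_groups(bundle$calls, g, cls, ty_cells)
      rows[[i]] <- test_gene(g, cls, bundle$ranks, bundle$consistent, grp,
                             n_quad = n_quad)
    }
    res <- do.call(rbind, rows)
    res <- .bh_within(res, res$alteration_class)
    res <- cbind(cancer_type = ty, res, stringsAsFactors = FALSE)
    out[[ty]] <- res
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$cancer_type, res$gene, res$alteration_class, method = "radix"), ,
      drop = FALSE]
}

#' Ablation variants: which stage buys the power?
#'
#' Four variants sharing the grouping, consistency-selection and testing
#' machinery:
#' \describe{
#'   \item{lmm_raw}{Gaussian random-intercept model on raw logFC values}
#'   \item{lmm_denoised}{Gaussian random-intercept model on batch-corrected
#'     logFC values}
#'   \item{nb_rank_raw}{NB random-intercept model on ranks of raw logFC}
#'   \item{nb_rank_denoised}{NB random-intercept model on ranks of corrected
#'     logFC -- identical to the main pipeline ([run_pancancer])}
#' }
#' Each variant selects consistent shRNAs from the rank matrix of its own
#' response matrix (raw or corrected), so the selection machinery is shared
#' while the response construction varies.
#'
#' @inheritParams run_pancancer
#' @param variant one of `"lmm_raw"`, `"lmm_denoised"`, `"nb_rank_raw"`,
#'   `"nb_rank_denoised"`.
#' @return data.frame in the results schema.
#' @export
run_ablation_variant <- function(variant, bundle, classes = .alteration_classes,
                                 alpha = 0.05, n_quad = 1L) {
  stopifnot(inherits(bundle, "nbdep_bundle"))
  variant <- match.arg(variant,
                       c("lmm_raw", "lmm_denoised", "nb_rank_raw", "nb_rank_denoised"))
  if (variant == "nb_rank_denoised")
    return(run_pancancer(bundle, classes = classes, alpha = alpha, n_quad = n_quad))
  classes <- match.arg(classes, .alteration_classes, several.ok = TRUE)

  values <- switch(variant,
                   lmm_raw = bundle$screen$logfc,
                   lmm_denoised = bundle$corrected$values,
                   nb_rank_raw = bundle$screen$logfc)
  rk <- rank_within_cell_line(values)
  gene_of <- stats::setNames(bundle$screen$annotations$gene,
                             bundle$screen$annotations$shrna_id)
  consistent <- select_consistent_shrnas(rk, gene_of)
  cells <- colnames(bundle$screen$logfc)
  genes <- sort(unique(bundle$screen$annotations$gene))

  rows <- list()
  i <- 0L
  for (g in genes) for (cls in classes) {
    i <- i + 1L
    grp <- build_test_groups(bundle$calls, g, cls, cells)
    if (variant == "nb_rank_raw") {
      rows[[i]] <- test_gene(g, cls, rk, consistent, grp, n_quad = n_quad)
    } else {
      rows[[i]] <- .test_gene_lmm(g, cls, values, consistent, grp)
    }
  }
  res <- do.call(rbind, rows)
  res <- .bh_within(res, res$alteration_class)
  res[order(res$gene, res$alteration_class, method = "radix"), , drop = FALSE]
}

# Gaussian-LMM analogue of test_gene for the lmm_* ablation variants:
# response is the (raw or corrected) logFC itself, H1 still beta < 0.
.test_gene_lmm <- function(gene, cls, values, consistent, groups) {
  if (length(groups$mutant) < 2L)
    return(.result_row(gene, cls, length(groups$mutant), length(groups$control),
                       skipped = "insufficient mutant group"))
  if (length(groups$control) < 2L)
    return(.result_row(gene, cls, length(groups$mutant), length(groups$control),
                       skipped = "insufficient wild-type group"))
  rkobj <- structure(list(ranks = values), class = "nbdep_ranks")
  a <- .assemble_gene_obs(gene, rkobj, consistent, groups$mutant, groups$control)
  if (a$n_mut < 2L || a$n_ctrl < 2L)
    return(.result_row(gene, cls, a$n_mut, a$n_ctrl, a$n_shrnas,
                       skipped = "insufficient observed values"))
  fit <- tryCatch(fit_gaussian_lmm(a$r, a$x, a$cell), error = function(e) e)
  if (inherits(fit, "error"))
    return(.result_row(gene, cls, a$n_mut, a$n_ctrl, a$n_shrnas,
                       skipped = paste0("fit error: ", conditionMessage(fit))))
  p <- wald_one_sided_p(fit$beta, fit$se_beta)
  .result_row(gene, cls, a$n_mut, a$n_ctrl, a$n_shrnas, fit = fit, p = p)
}
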