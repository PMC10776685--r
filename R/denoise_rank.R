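# Steps 2-3: batch-effect removal, within-cell-line ranking, and selection
# of each gene's concordant shRNAs.
#
# Pool membership and seed stability are attributes of the shRNA, so the
# batch regression runs per CELL LINE across its observed shRNAs:
#   y_s = alpha_c + delta_c[pool(s)] + gamma_c * stab(s) + eps
# with the pool factor coded sum-to-zero and stability centred over the
# fitted shRNAs, and the corrected value defined as
#   y_s - delta_c[pool(s)] - gamma_c * (stab(s) - mean stab),
# i.e. residual + intercept. This preserves each cell line's mean, and the
# downstream within-cell-line ranks are invariant to the centring choice.

#' Remove pool and seed-stability batch effects
#'
#' @param screen [screen_dataset()] with unique shRNA rows (after
#'   [collapse_duplicate_measurements]).
#' @param stability [seed_stability_table()]. shRNAs whose seed is missing or
#'   absent from the table are assigned the table's mean stability
#'   (equivalently zero after centring).
#' @return object of class `nbdep_corrected` whose `values` matrix has the
#'   same shape and missingness pattern as `screen$logfc`. Cell lines whose
#'   observed shRNAs span a single pool lose the pool term; constant
#'   stability drops the stability term (one summary warning each).
#' @export
remove_batch_effects <- function(screen, stability) {
  stopifnot(inherits(screen, "nbdep_screen"),
            inherits(stability, "nbdep_seed_stability"))
  if (anyDuplicated(rownames(screen$logfc)))
    stop("collapse duplicate readouts before batch correction")
  ann <- screen$annotations
  stab <- unname(stability$stability[ann$seed])
  stab[is.na(stab)] <- mean(stability$stability)
  pool <- ann$pool
  y <- screen$logfc
  corrected <- y
  n_pool_dropped <- 0L
  n_stab_dropped <- 0L
  for (j in seq_len(ncol(y))) {
    obs <- which(!is.na(y[, j]))
    if (length(obs) < 2L) next
    po <- factor(pool[obs])
    stc <- stab[obs] - mean(stab[obs])
    X <- matrix(1, length(obs), 1)
    if (nlevels(po) > 1L) {
      Xp <- stats::model.matrix(~po, contrasts.arg = list(po = "contr.sum"))
      X <- cbind(X, Xp[, -1, drop = FALSE])
    } else n_pool_dropped <- n_pool_dropped + 1L
    if (stats::sd(stc) > 0) X <- cbind(X, stc) else n_stab_dropped <- n_stab_dropped + 1L
    if (ncol(X) == 1L) next                      # nothing estimable: identity
    fit <- stats::lm.fit(X, y[obs, j])
    corrected[obs, j] <- fit$residuals + fit$coefficients[1]
  }
  if (n_pool_dropped > 0L)
    warning(n_pool_dropped, " cell line(s) span a single pool; pool term dropped there")
  if (n_stab_dropped > 0L)
    warning(n_stab_dropped, " cell line(s) have constant seed stability; stability term dropped there")
  structure(list(values = corrected), class = "nbdep_corrected")
}

#' Rank corrected logFC values within each cell line
#'
#' Ascending ranks over the observed entries of each cell line: the most
#' depleted (most negative) corrected value gets rank 1. Missing entries
#' stay missing and observed ranks are contiguous `1..n_observed`. Ties are
#' broken deterministically by shRNA id (C-locale lexicographic order).
#' Ranking is global per cell line over all retained shRNAs of all genes and
#' is performed once, before consistency selection, never recomputed.
#'
#' @param corrected `nbdep_corrected` object (or a plain numeric matrix with
#'   shRNA rownames).
#' @return object of class `nbdep_ranks` with integer matrix `ranks`.
#' @export
rank_within_cell_line <- function(corrected) {
  v <- if (inherits(corrected, "nbdep_corrected")) corrected$values else as.matrix(corrected)
  ids <- rownames(v)
  rk <- matrix(NA_integer_, nrow(v), ncol(v), dimnames = dimnames(v))
  for (j in seq_len(ncol(v))) {
    obs <- which(!is.na(v[, j]))
    if (!length(obs)) next
    ord <- obs[order(v[obs, j], ids[obs], method = "radix")]
    rk[ord, j] <- seq_along(ord)
  }
  structure(list(ranks = rk), class = "nbdep_ranks")
}

#' Select each gene's concordant shRNAs
#'
#' For every gene, the per-cell-line average rank over the gene's shRNAs
#' defines the gene's mean rank profile (the shRNA under consideration is
#' included; no leave-one-out). Each shRNA's Pearson correlation with that
#' profile is computed over cell lines where both are observed
#' (pairwise-complete); shRNAs with fewer than 3 paired observations or a
#' zero-variance vector get correlation -Inf and are never selected ahead of
#' defined ones. The `ceiling(n/2)` shRNAs with the highest correlation are
#' retained, where `n` counts the gene's shRNAs with at least one observed
#' rank; a single-shRNA gene retains its shRNA. Ties at the cutoff are broken
#' by shRNA id.
#'
#' @param ranks `nbdep_ranks` object.
#' @param gene_of named character vector mapping shRNA id to gene.
#' @return data.frame of class `nbdep_consistent` with columns
#'   `gene, shrna_id, correlation, retained`, ordered by gene, then
#'   decreasing correlation, then shRNA id.
#' @export
select_consistent_shrnas <- function(ranks, gene_of) {
  stopifnot(inherits(ranks, "nbdep_ranks"))
  R <- ranks$ranks
  ids <- rownames(R)
  if (!all(ids %in% names(gene_of))) stop("gene_of must cover every ranked shRNA")
  genes <- split(ids, as.character(gene_of[ids]))
  n_undefined <- 0L
  out <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g_ids <- genes[[gi]]
    sub <- R[g_ids, , drop = FALSE]
    has_obs <- rowSums(!is.na(sub)) > 0L
    g_ids <- g_ids[has_obs]
    if (!length(g_ids)) next
    sub <- sub[g_ids, , drop = FALSE]
    mp <- colMeans(sub, na.rm = TRUE)           # NaN where no shRNA observed
    cors <- vapply(seq_along(g_ids), function(i) {
      x <- sub[i, ]
      p <- !is.na(x) & is.finite(mp)
      if (sum(p) < 3L) return(-Inf)
      if (stats::sd(x[p]) == 0 || stats::sd(mp[p]) == 0) return(-Inf)
      stats::cor(x[p], mp[p])
    }, numeric(1))
    n_undefined <- n_undefined + sum(!is.finite(cors))
    ord <- order(-cors, g_ids, method = "radix")
    n_keep <- ceiling(length(g_ids) / 2)
    out[[gi]] <- data.frame(gene = names(genes)[gi],
                            shrna_id = g_ids[ord],
                            correlation = cors[ord],
                            retained = seq_along(ord) <= n_keep,
                            stringsAsFactors = FALSE)
  }
  if (n_undefined > 0L)
    warning(n_undefined, " shRNA(s) with undefined rank correlation (",
            "fewer than 3 paired observations or zero variance); assigned -Inf")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("nbdep_consistent", "data.frame")
  res
}

#' Retained shRNA ids of a gene
#' @param consistent `nbdep_consistent` data.frame.
#' @param gene gene symbol.
#' @return character vector of retained shRNA ids (possibly empty).
#' @export
retained_shrnas <- function(consistent, gene) {
  consistent$shrna_id[consistent$gene == gene & consistent$retained]
}
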