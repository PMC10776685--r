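# Step 1 of the pipeline: cell-line, gene and shRNA filters, plus the
# collapse of replicated readouts. Filters only ever remove rows/columns;
# only duplicate collapsing touches retained values (by averaging).

#' Remove hypermutated cell lines
#'
#' A cell line is hypermutated if its mutation burden (number of mutation
#' records of any classification) is strictly more than three standard
#' deviations above the mean burden across the supplied cell lines. The
#' threshold is computed once on the original burdens (no iteration); the
#' standard deviation uses the conventional n-1 denominator.
#'
#' @param mutations [mutation_table()] object.
#' @param cell_lines character vector of candidate cell lines; lines absent
#'   from the table have burden zero.
#' @return list with character vectors `kept` and `removed`
#'   (`kept` + `removed` partition the input) and the numeric `threshold`.
#' @export
remove_hypermutated_cell_lines <- function(mutations, cell_lines) {
  stopifnot(inherits(mutations, "nbdep_mutation_table"))
  cell_lines <- as.character(cell_lines)
  if (length(cell_lines) < 2L) {
    warning("fewer than 2 cell lines: burden sd undefined, keeping all")
    return(list(kept = cell_lines, removed = character(0), threshold = Inf))
  }
  tab <- table(factor(mutations$cell_line, levels = cell_lines))
  burden <- as.numeric(tab)
  thr <- mean(burden) + 3 * stats::sd(burden)
  removed <- cell_lines[burden > thr]
  list(kept = setdiff(cell_lines, removed), removed = removed, threshold = thr)
}

.subset_screen_rows <- function(screen, keep_ids) {
  keep_ann <- screen$annotations$shrna_id %in% keep_ids
  keep_row <- rownames(screen$logfc) %in% keep_ids
  screen_dataset(screen$annotations[keep_ann, , drop = FALSE],
                 screen$logfc[keep_row, , drop = FALSE],
                 allow_duplicate_rows = TRUE)
}

#' Drop genes without molecular profiling data
#'
#' A gene is retained iff it appears in the mutation table's gene universe
#' AND the copy-number table's gene universe -- presence as a profiled
#' entity, not presence of a non-zero call (a gene that is GISTIC 0
#' everywhere is still profiled). All shRNAs of a dropped gene are removed.
#'
#' @param screen [screen_dataset()] object.
#' @param mutations [mutation_table()] object.
#' @param cn [copy_number_table()] object.
#' @return filtered [screen_dataset()].
#' @export
filter_genes_without_molecular_data <- function(screen, mutations, cn) {
  stopifnot(inherits(screen, "nbdep_screen"),
            inherits(mutations, "nbdep_mutation_table"),
            inherits(cn, "nbdep_copy_number_table"))
  profiled <- intersect(unique(mutations$gene), unique(cn$gene))
  keep_gene <- screen$annotations$gene %in% profiled
  if (!any(keep_gene)) warning("no gene has both mutation and copy-number data; empty dataset")
  .subset_screen_rows(screen, screen$annotations$shrna_id[keep_gene])
}

#' Drop shRNAs with missing or low initial abundance
#'
#' An shRNA is kept iff its initial abundance is present and at least
#' `min_abundance` ("below 50" read as strictly less than 50).
#'
#' @param screen [screen_dataset()] object.
#' @param min_abundance minimum retained abundance count (default 50).
#' @return filtered [screen_dataset()].
#' @export
filter_shrnas_by_abundance <- function(screen, min_abundance = 50) {
  stopifnot(inherits(screen, "nbdep_screen"))
  ab <- screen$annotations$initial_abundance
  keep <- !is.na(ab) & ab >= min_abundance
  .subset_screen_rows(screen, screen$annotations$shrna_id[keep])
}

#' Average replicated readouts of an shRNA
#'
#' When a screen reports multiple readouts for the same shRNA, the replicated
#' logFC values are replaced, per cell line, by their arithmetic mean over
#' the observed readouts (all-missing stays missing), leaving one row per
#' shRNA. Replicated rows must share gene/pool/seed annotations.
#'
#' @param screen [screen_dataset()] possibly holding duplicate logfc rows.
#' @return [screen_dataset()] with unique shRNA rows; attribute
#'   `n_collapsed` counts the extra rows removed.
#' @export
collapse_duplicate_measurements <- function(screen) {
  stopifnot(inherits(screen, "nbdep_screen"))
  ids <- rownames(screen$logfc)
  n_extra <- length(ids) - length(unique(ids))
  if (n_extra == 0L) {
    # keep matrix rows aligned with annotation order
    out <- screen_dataset(screen$annotations,
                          screen$logfc[screen$annotations$shrna_id, , drop = FALSE])
    attr(out, "n_collapsed") <- 0L
    return(out)
  }
  grp <- factor(ids, levels = screen$annotations$shrna_id)
  obs <- rowsum((!is.na(screen$logfc)) * 1, grp, reorder = FALSE)
  tot <- rowsum(ifelse(is.na(screen$logfc), 0, screen$logfc), grp, reorder = FALSE)
  mat <- tot / obs            # 0/0 -> NaN where all readouts missing
  mat[obs == 0] <- NA_real_
  mat <- mat[screen$annotations$shrna_id, , drop = FALSE]
  out <- screen_dataset(screen$annotations, mat)
  attr(out, "n_collapsed") <- n_extra
  out
}

#' Run the full preprocessing step
#'
#' Applies, in this fixed order: (1) hypermutated cell-line removal,
#' (2) removal of genes without mutation or copy-number data, (3) removal of
#' shRNAs with missing or low initial abundance, (4) averaging of replicated
#' readouts. Re-running on its own output is the identity.
#'
#' @param screen [screen_dataset()] object (duplicates allowed).
#' @param mutations [mutation_table()] object.
#' @param cn [copy_number_table()] object.
#' @param min_abundance abundance threshold passed to
#'   [filter_shrnas_by_abundance].
#' @return list with the filtered `screen` and a `report`
#'   (class `nbdep_preprocess_report`) holding the removal counts and final
#'   dimensions.
#' @export
preprocess_screen <- function(screen, mutations, cn, min_abundance = 50) {
  stopifnot(inherits(screen, "nbdep_screen"))
  cl <- colnames(screen$logfc)
  hm <- remove_hypermutated_cell_lines(mutations, cl)
  s <- screen_dataset(screen$annotations,
                      screen$logfc[, hm$kept, drop = FALSE],
                      allow_duplicate_rows = TRUE)
  n_sh_before <- length(unique(s$annotations$shrna_id))
  s <- filter_genes_without_molecular_data(s, mutations, cn)
  n_sh_genes <- length(unique(s$annotations$shrna_id))
  n_genes_removed <- length(unique(screen$annotations$gene)) -
    length(unique(s$annotations$gene))
  s <- filter_shrnas_by_abundance(s, min_abundance = min_abundance)
  n_sh_ab <- length(unique(s$annotations$shrna_id))
  s <- collapse_duplicate_measurements(s)
  report <- structure(list(
    n_cell_lines_removed_hypermutated = length(hm$removed),
    n_genes_removed_no_molecular_data = n_genes_removed,
    n_shrnas_removed_abundance = n_sh_genes - n_sh_ab,
    n_duplicates_collapsed = attr(s, "n_collapsed"),
    n_shrnas = nrow(s$logfc),
    n_genes = length(unique(s$annotations$gene)),
    n_cell_lines = ncol(s$logfc)
  ), class = "nbdep_preprocess_report")
  list(screen = s, report = report)
}

#' @export
print.nbdep_preprocess_report <- function(x, ...) {
  cat("preprocessing report:\n",
      "  hypermutated cell lines removed: ", x$n_cell_lines_removed_hypermutated, "\n",
      "  genes without molecular data removed: ", x$n_genes_removed_no_molecular_data, "\n",
      "  shRNAs removed by abundance filter: ", x$n_shrnas_removed_abundance, "\n",
      "  replicated readout rows collapsed: ", x$n_duplicates_collapsed, "\n",
      "  final: ", x$n_shrnas, " shRNAs, ", x$n_genes, " genes, ",
      x$n_cell_lines, " cell lines\n", sep = "")
  invisible(x)
}
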