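# Domain containers and TSV readers/writers.
#
# All identifiers are opaque strings; no gene-symbol normalisation is
# attempted. Missing values are the empty field or "NA" on read and are
# written back as "NA". Seeds are stored uppercase with U unified to T.

.normalize_seed <- function(seed, id = NULL) {
  seed <- toupper(as.character(seed))
  seed <- chartr("U", "T", seed)
  seed[!nzchar(seed)] <- NA_character_
  bad <- !is.na(seed) & (nchar(seed) != 7L | grepl("[^ACGT]", seed))
  if (any(bad)) {
    who <- if (!is.null(id)) paste0(" (shRNA ", paste(id[bad][1:min(3, sum(bad))], collapse = ", "), ")") else ""
    stop("invalid seed sequence: seeds must be 7-mers over A/C/G/T or missing", who)
  }
  seed
}

#' Construct an shRNA screen dataset
#'
#' Bundles per-shRNA annotations (target gene, pool label, 7-mer seed,
#' initial library abundance) with a logFC matrix over cell lines. This is
#' the raw observable of a pooled shRNA viability screen: entry `[s, c]` is
#' the log fold change of shRNA `s`'s read count in cell line `c` relative to
#' its initial abundance.
#'
#' @param annotations data.frame with columns `shrna_id`, `gene`, `pool`,
#'   `seed`, `initial_abundance`; one row per distinct shRNA.
#' @param logfc numeric matrix, rownames are shRNA ids (duplicates allowed
#'   only with `allow_duplicate_rows = TRUE`, e.g. replicated readouts prior
#'   to [collapse_duplicate_measurements]), colnames are cell lines.
#' @param allow_duplicate_rows logical; permit repeated shRNA rows in `logfc`.
#' @return An object of class `nbdep_screen` with elements `annotations` and
#'   `logfc`.
#' @seealso [load_screen_dataset], [preprocess_screen]
#' @export
screen_dataset <- function(annotations, logfc, allow_duplicate_rows = FALSE) {
  req <- c("shrna_id", "gene", "pool", "seed", "initial_abundance")
  miss <- setdiff(req, names(annotations))
  if (length(miss)) stop("annotations missing column(s): ", paste(miss, collapse = ", "))
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)[req]
  annotations$shrna_id <- as.character(annotations$shrna_id)
  annotations$gene <- as.character(annotations$gene)
  annotations$pool <- as.character(annotations$pool)
  if (anyDuplicated(annotations$shrna_id))
    stop("duplicated shrna_id in annotations: ",
         annotations$shrna_id[duplicated(annotations$shrna_id)][1])
  if (anyNA(annotations$gene) || anyNA(annotations$pool))
    stop("every shRNA must have a gene and a pool label")
  annotations$seed <- .normalize_seed(annotations$seed, annotations$shrna_id)
  ab <- annotations$initial_abundance
  if (!is.numeric(ab)) stop("initial_abundance must be numeric (or NA)")
  if (any(!is.na(ab) & ab < 0)) stop("initial_abundance must be non-negative")

  logfc <- as.matrix(logfc)
  storage.mode(logfc) <- "double"
  if ((nrow(logfc) > 0L && is.null(rownames(logfc))) ||
      (ncol(logfc) > 0L && is.null(colnames(logfc))))
    stop("logfc must have shRNA rownames and cell-line colnames")
  if (is.null(rownames(logfc))) rownames(logfc) <- character(0)
  if (is.null(colnames(logfc))) colnames(logfc) <- character(0)
  if (anyDuplicated(colnames(logfc)))
    stop("duplicated cell-line identifiers in logfc columns")
  unknown <- setdiff(rownames(logfc), annotations$shrna_id)
  if (length(unknown))
    stop("shRNA in logfc matrix without annotation: ", unknown[1])
  if (!allow_duplicate_rows && anyDuplicated(rownames(logfc)))
    stop("duplicated shRNA rows in logfc; load with duplicates and call ",
         "collapse_duplicate_measurements()")
  absent <- setdiff(annotations$shrna_id, rownames(logfc))
  if (length(absent))
    stop("annotated shRNA absent from logfc matrix: ", absent[1])

  structure(list(annotations = annotations, logfc = logfc),
            class = "nbdep_screen")
}

#' @export
print.nbdep_screen <- function(x, ...) {
  cat("nbdep screen dataset:", nrow(x$logfc), "shRNA rows (",
      nrow(x$annotations), "distinct ) x", ncol(x$logfc), "cell lines;",
      length(unique(x$annotations$gene)), "genes;",
      sum(is.na(x$logfc)), "missing logFC entries\n")
  invisible(x)
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    na.strings = c("NA", ""), colClasses = "character",
                    stringsAsFactors = FALSE)
}

.as_num <- function(x, what, rows = seq_along(x)) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop("non-numeric ", what, " at row ", rows[bad[1]], " (value '", x[bad[1]], "')")
  out
}

#' Load an shRNA screen from annotation and logFC tables
#'
#' @param path_annotations TSV with columns
#'   `shrna_id, gene, pool, seed, initial_abundance`.
#' @param path_logfc TSV whose first column is `shrna_id` and remaining
#'   columns are cell lines. Duplicate `shrna_id` rows (replicated readouts)
#'   are preserved, not collapsed; see [collapse_duplicate_measurements].
#' @return [screen_dataset()] object.
#' @export
load_screen_dataset <- function(path_annotations, path_logfc) {
  ann <- .read_tsv(path_annotations)
  req <- c("shrna_id", "gene", "pool", "seed", "initial_abundance")
  miss <- setdiff(req, names(ann))
  if (length(miss))
    stop("malformed annotation header: missing column(s) ", paste(miss, collapse = ", "))
  ann$initial_abundance <- .as_num(ann$initial_abundance, "initial_abundance")
  # annotation tables may carry one row per readout; fields must then agree
  if (anyDuplicated(ann$shrna_id)) {
    key <- ann$shrna_id
    for (f in c("gene", "pool", "seed")) {
      n_distinct <- tapply(ann[[f]], key, function(v) length(unique(v)))
      if (any(n_distinct > 1))
        stop("conflicting ", f, " annotation for duplicated shRNA ",
             names(n_distinct)[n_distinct > 1][1])
    }
    ab <- tapply(ann$initial_abundance, key, function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    ann <- ann[!duplicated(ann$shrna_id), , drop = FALSE]
    ann$initial_abundance <- as.numeric(ab[ann$shrna_id])
  }

  lf <- .read_tsv(path_logfc)
  if (names(lf)[1] != "shrna_id")
    stop("malformed logFC header: first column must be shrna_id, got '", names(lf)[1], "'")
  if (ncol(lf) < 2) stop("malformed logFC table: no cell-line columns")
  ids <- lf$shrna_id
  mat <- matrix(NA_real_, nrow(lf), ncol(lf) - 1L,
                dimnames = list(ids, names(lf)[-1]))
  for (j in seq_len(ncol(mat)))
    mat[, j] <- .as_num(lf[[j + 1L]], paste0("logFC in column '", colnames(mat)[j], "'"))
  screen_dataset(ann, mat, allow_duplicate_rows = TRUE)
}

#' Write a screen dataset back to its two-table TSV representation
#'
#' Numeric values are written with 17 significant digits so that
#' load -> write -> load is the identity.
#'
#' @param screen [screen_dataset()] object.
#' @param path_annotations,path_logfc output TSV paths.
#' @export
write_screen_dataset <- function(screen, path_annotations, path_logfc) {
  stopifnot(inherits(screen, "nbdep_screen"))
  .write_tsv(screen$annotations, path_annotations)
  lf <- data.frame(shrna_id = rownames(screen$logfc), screen$logfc,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(lf, path_logfc)
  invisible(NULL)
}

.fmt_num <- function(x) {
  out <- vapply(x, function(v) if (is.na(v)) "NA" else sprintf("%.17g", v), "")
  out
}

.write_tsv <- function(df, path) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- .fmt_num(df[[j]]) else {
      v <- as.character(df[[j]]); v[is.na(v)] <- "NA"; df[[j]] <- v
    }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Seed thermodynamic-stability table
#'
#' Maps each 7-mer seed to the thermodynamic stability of its pairing
#' (as supplied, arbitrary energy units). At most 4^7 = 16384 entries.
#'
#' @param seed character vector of 7-mers (U or T alphabet).
#' @param stability numeric stability values.
#' @return object of class `nbdep_seed_stability` with element `stability`,
#'   a named numeric vector keyed by seed.
#' @export
seed_stability_table <- function(seed, stability) {
  seed <- .normalize_seed(seed)
  if (anyNA(seed)) stop("stability table seeds must not be missing")
  if (anyDuplicated(seed)) stop("duplicated seed in stability table: ", seed[duplicated(seed)][1])
  stability <- as.numeric(stability)
  if (anyNA(stability)) stop("missing stability value")
  structure(list(stability = stats::setNames(stability, seed)),
            class = "nbdep_seed_stability")
}

#' Load a seed-stability TSV (columns `seed`, `stability`)
#' @param path TSV path.
#' @return [seed_stability_table()] object.
#' @export
load_seed_stability <- function(path) {
  df <- .read_tsv(path)
  miss <- setdiff(c("seed", "stability"), names(df))
  if (length(miss)) stop("malformed stability header: missing ", paste(miss, collapse = ", "))
  seed_stability_table(df$seed, .as_num(df$stability, "stability"))
}

#' @rdname load_alteration_inputs
#' @param gene,cell_line,variant_classification character vectors (one entry
#'   per mutation record).
#' @export
mutation_table <- function(gene, cell_line, variant_classification) {
  df <- data.frame(gene = as.character(gene),
                   cell_line = as.character(cell_line),
                   variant_classification = as.character(variant_classification),
                   stringsAsFactors = FALSE)
  if (anyNA(df)) stop("mutation records must be complete")
  class(df) <- c("nbdep_mutation_table", "data.frame")
  df
}

#' @rdname load_alteration_inputs
#' @param gistic integer GISTIC2 calls in -2..2.
#' @export
copy_number_table <- function(gene, cell_line, gistic) {
  g <- suppressWarnings(as.numeric(gistic))
  bad <- which(is.na(g) | g != round(g) | g < -2 | g > 2)
  if (length(bad))
    stop("invalid GISTIC value '", gistic[bad[1]], "' at row ", bad[1],
         " (must be an integer in -2..2)")
  df <- data.frame(gene = as.character(gene), cell_line = as.character(cell_line),
                   gistic = as.integer(g), stringsAsFactors = FALSE)
  key <- paste(df$gene, df$cell_line, sep = "\r")
  if (anyDuplicated(key)) {
    conflict <- tapply(df$gistic, key, function(v) length(unique(v)) > 1)
    if (any(conflict))
      stop("conflicting GISTIC values for (gene, cell line): ",
           gsub("\r", ", ", names(conflict)[conflict][1]))
    df <- df[!duplicated(key), , drop = FALSE]
  }
  class(df) <- c("nbdep_copy_number_table", "data.frame")
  df
}

#' @rdname load_alteration_inputs
#' @param cancer_type character vector of cancer-type labels.
#' @export
cancer_type_map <- function(cell_line, cancer_type) {
  cl <- as.character(cell_line); ty <- as.character(cancer_type)
  if (anyDuplicated(cl)) {
    conflict <- tapply(ty, cl, function(v) length(unique(v)) > 1)
    if (any(conflict))
      stop("cell line with more than one cancer-type label: ",
           names(conflict)[conflict][1])
    keep <- !duplicated(cl); cl <- cl[keep]; ty <- ty[keep]
  }
  structure(list(type_of = stats::setNames(ty, cl)), class = "nbdep_cancer_types")
}

#' Load mutation, copy-number and cancer-type tables
#'
#' Expected TSV columns: mutations `gene, cell_line, variant_classification`
#' (MAF-like minimal); copy number `gene, cell_line, gistic` with GISTIC2
#' calls in -2..2; cancer types `cell_line, cancer_type`.
#'
#' @param path_mut,path_cn,path_types input TSV paths.
#' @return list with elements `mutations`, `copy_number`, `cancer_types`.
#' @export
load_alteration_inputs <- function(path_mut, path_cn, path_types) {
  m <- .read_tsv(path_mut)
  miss <- setdiff(c("gene", "cell_line", "variant_classification"), names(m))
  if (length(miss)) stop("malformed mutation header: missing ", paste(miss, collapse = ", "))
  cn <- .read_tsv(path_cn)
  miss <- setdiff(c("gene", "cell_line", "gistic"), names(cn))
  if (length(miss)) stop("malformed GISTIC header: missing ", paste(miss, collapse = ", "))
  ty <- .read_tsv(path_types)
  miss <- setdiff(c("cell_line", "cancer_type"), names(ty))
  if (length(miss)) stop("malformed cancer-type header: missing ", paste(miss, collapse = ", "))
  list(mutations = mutation_table(m$gene, m$cell_line, m$variant_classification),
       copy_number = copy_number_table(cn$gene, cn$cell_line, cn$gistic),
       cancer_types = cancer_type_map(ty$cell_line, ty$cancer_type))
}

.results_columns <- c("gene", "alteration_class", "n_mutant", "n_wildtype",
                      "n_shrnas_used", "beta", "se_beta", "theta", "sigma2",
                      "p_value", "q_value", "converged", "skipped_reason")

#' Write per-gene test results to TSV
#'
#' One row per (gene, alteration class), ordered by gene then class. Columns:
#' `gene, alteration_class, n_mutant, n_wildtype, n_shrnas_used, beta,
#' se_beta, theta, sigma2, p_value, q_value, converged, skipped_reason`.
#' Numeric columns carry 17 significant digits so a read-back reproduces the
#' written values.
#'
#' @param results data.frame of gene test results (e.g. from [run_pancancer]).
#' @param path output TSV path.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results) || nrow(as.data.frame(results)) == 0L) {
    cat(paste(.results_columns, collapse = "\t"), "\n", sep = "", file = path)
    return(invisible(NULL))
  }
  results <- as.data.frame(results, stringsAsFactors = FALSE)
  extra <- setdiff(.results_columns, names(results))
  if (length(extra)) stop("results missing column(s): ", paste(extra, collapse = ", "))
  results <- results[order(results$gene, results$alteration_class, method = "radix"),
                     .results_columns, drop = FALSE]
  .write_tsv(results, path)
  invisible(NULL)
}

#' Read back a results TSV written by [write_results_table]
#' @param path TSV path.
#' @return data.frame in the results schema.
#' @export
read_results_table <- function(path) {
  df <- .read_tsv(path)
  miss <- setdiff(.results_columns, names(df))
  if (length(miss)) stop("malformed results header: missing ", paste(miss, collapse = ", "))
  for (f in c("n_mutant", "n_wildtype", "n_shrnas_used"))
    df[[f]] <- as.integer(.as_num(df[[f]], f))
  for (f in c("beta", "se_beta", "theta", "sigma2", "p_value", "q_value"))
    df[[f]] <- .as_num(df[[f]], f)
  df$converged <- as.logical(df$converged)
  df$skipped_reason[is.na(df$skipped_reason)] <- ""
  df
}
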