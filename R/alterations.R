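# Classification of (gene, cell line) pairs into alteration classes and
# construction of mutant / wild-type test groups.
#
# Categories follow the three tested alteration classes: missense mutations,
# non-missense mutations (truncating/structural coding events), and
# copy-number amplification (GISTIC2 value 2). Deep deletion (GISTIC2 -2)
# is tracked because it breaks wild-type status, but is not itself tested.

.non_missense_classes <- c(
  "start codon deletion", "stop codon deletion",
  "start codon insertion", "stop codon insertion",
  "frameshift deletion", "frameshift insertion",
  "in frame deletion", "in frame insertion",
  "nonsense mutation", "splice site"
)

.normalize_classification <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[-_[:space:]]+", " ", x)
  trimws(x)
}

#' Default MAF-dialect classification aliases
#'
#' MAF dialects name the same variant classes differently (e.g. DepMap's
#' `Frame_Shift_Del`). The default alias table, shipped at
#' `inst/extdata/classification_aliases.tsv`, maps normalised dialect
#' strings to the canonical class names used here. Matching is
#' case-insensitive with `-`, `_` and whitespace unified.
#'
#' @return data.frame with columns `alias`, `category`.
#' @export
default_classification_aliases <- function() {
  if (is.null(.nbdep_cache$aliases)) {
    path <- system.file("extdata", "classification_aliases.tsv", package = "nbdep")
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    df$alias <- .normalize_classification(df$alias)
    df$category <- .normalize_classification(df$category)
    .nbdep_cache$aliases <- df
  }
  .nbdep_cache$aliases
}

#' Classify gene-by-cell-line alteration status
#'
#' Builds, for every (gene, cell line) pair, four non-exclusive flags:
#' \describe{
#'   \item{missense}{any mutation record classified "missense mutation"}
#'   \item{non_missense}{any record among start/stop codon deletions and
#'     insertions, frameshift deletions/insertions, in-frame
#'     deletions/insertions, nonsense mutation, splice site}
#'   \item{amplification}{GISTIC2 call 2}
#'   \item{deep_deletion}{GISTIC2 call -2}
#' }
#' A pair is wild-type iff all four flags are false. Unrecognised
#' classification strings (e.g. silent or UTR variants) create no flag and
#' are tallied in the `unrecognized` element. Classification is a pure
#' function of the two tables; input row order never changes the output.
#'
#' @param mutations [mutation_table()] object.
#' @param cn [copy_number_table()] object.
#' @param aliases optional alias data.frame (columns `alias`, `category`);
#'   defaults to [default_classification_aliases()].
#' @return object of class `nbdep_alteration_calls`: per flag, a named list
#'   gene -> sorted cell lines carrying that flag, plus the profiled `genes`
#'   and the `unrecognized` tally.
#' @export
classify_gene_cell_alterations <- function(mutations, cn,
                                           aliases = default_classification_aliases()) {
  stopifnot(inherits(mutations, "nbdep_mutation_table"),
            inherits(cn, "nbdep_copy_number_table"))
  cls <- .normalize_classification(mutations$variant_classification)
  if (!is.null(aliases) && nrow(aliases)) {
    idx <- match(cls, aliases$alias)
    cls[!is.na(idx)] <- aliases$category[idx[!is.na(idx)]]
  }
  is_mis <- cls == "missense mutation"
  is_non <- cls %in% .non_missense_classes
  unrec <- table(mutations$variant_classification[!is_mis & !is_non])

  flag_sets <- function(gene, cell) {
    if (!length(gene)) return(list())
    lapply(split(cell, gene), function(v) sort(unique(v)))
  }
  calls <- list(
    missense = flag_sets(mutations$gene[is_mis], mutations$cell_line[is_mis]),
    non_missense = flag_sets(mutations$gene[is_non], mutations$cell_line[is_non]),
    amplification = flag_sets(cn$gene[cn$gistic == 2L], cn$cell_line[cn$gistic == 2L]),
    deep_deletion = flag_sets(cn$gene[cn$gistic == -2L], cn$cell_line[cn$gistic == -2L]),
    genes = sort(union(unique(mutations$gene), unique(cn$gene))),
    unrecognized = unrec
  )
  class(calls) <- "nbdep_alteration_calls"
  calls
}

#' Flags of one (gene, cell line) pair
#' @param calls `nbdep_alteration_calls` object.
#' @param gene,cell_line identifiers.
#' @return named logical vector over the four flags plus `wild_type`.
#' @export
alteration_flags <- function(calls, gene, cell_line) {
  f <- vapply(c("missense", "non_missense", "amplification", "deep_deletion"),
              function(k) cell_line %in% calls[[k]][[gene]], logical(1))
  c(f, wild_type = !any(f))
}

#' Build mutant / control groups for one gene and alteration class
#'
#' Mutant cell lines carry the tested class's flag for the gene; control
#' cell lines are strictly wild-type (no flag of any class, deep deletion
#' included); lines carrying only other alteration classes are excluded from
#' both groups. A gene-class combination is testable iff at least two mutant
#' and two control lines exist.
#'
#' @param calls `nbdep_alteration_calls` object.
#' @param gene gene symbol.
#' @param cls one of `"missense"`, `"non_missense"`, `"amplification"`
#'   (deep deletion only defines wild-type status and is not tested).
#' @param cell_lines cell lines with screen data.
#' @return object of class `nbdep_test_groups`: `mutant`, `control`,
#'   `excluded` (sorted character vectors partitioning `cell_lines`) and the
#'   logical `testable`.
#' @export
build_test_groups <- function(calls, gene, cls, cell_lines) {
  stopifnot(inherits(calls, "nbdep_alteration_calls"))
  cls <- match.arg(cls, c("missense", "non_missense", "amplification"))
  cell_lines <- as.character(cell_lines)
  flagged <- unique(unlist(lapply(
    c("missense", "non_missense", "amplification", "deep_deletion"),
    function(k) calls[[k]][[gene]]), use.names = FALSE))
  mutant <- sort(intersect(cell_lines, calls[[cls]][[gene]] %||% character(0)))
  control <- sort(setdiff(cell_lines, flagged))
  excluded <- sort(setdiff(intersect(cell_lines, flagged), mutant))
  structure(list(gene = gene, class = cls, mutant = mutant, control = control,
                 excluded = excluded,
                 testable = length(mutant) >= 2L && length(control) >= 2L),
            class = "nbdep_test_groups")
}
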