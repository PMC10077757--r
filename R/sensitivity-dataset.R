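#' Bundle an AUC matrix with cell-line and compound annotations
#'
#' A sensitivity dataset is the central container for panel-level analyses:
#' a cell-line-by-compound matrix of dose-response AUC fractions (lower =
#' more sensitive) together with per-line metadata (pediatric flag, tumor
#' type, mutation flags) and per-compound annotations (target, target
#' pathway). Missing AUC entries are `NA`, never silently zero.
#'
#' @param auc Numeric matrix, rows = cell lines, columns = compounds, with
#'   dimnames; values in `[0, 1]` or `NA`.
#' @param cell_meta Data frame with columns `cell_line`, logical
#'   `pediatric`, `tumor_type`, plus any number of logical mutation-flag
#'   columns (e.g. `STAG2`). One row per row of `auc`.
#' @param compound_meta Data frame with columns `compound`, `target`,
#'   `target_pathway`. One row per column of `auc`.
#' @return An object of class `sensitivity_dataset` (a list with elements
#'   `auc`, `cell_meta`, `compound_meta`).
#' @export
sensitivity_dataset <- function(auc, cell_meta, compound_meta) {
  if (!is.matrix(auc) || is.null(rownames(auc)) || is.null(colnames(auc))) {
    abort("auc must be a matrix with cell-line rownames and compound colnames")
  }
  if (anyDuplicated(rownames(auc))) abort("duplicated cell_line identifiers in auc")
  if (anyDuplicated(colnames(auc))) abort("duplicated compound identifiers in auc")
  rng <- range(auc, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) abort("AUC values must lie in [0, 1] (or be NA)")
  cell_meta <- tibble::as_tibble(cell_meta)
  compound_meta <- tibble::as_tibble(compound_meta)
  need_cell <- c("cell_line", "pediatric", "tumor_type")
  if (!all(need_cell %in% names(cell_meta))) {
    abort(paste0("cell_meta must contain columns: ",
                 paste(need_cell, collapse = ", ")))
  }
  need_cpd <- c("compound", "target", "target_pathway")
  if (!all(need_cpd %in% names(compound_meta))) {
    abort(paste0("compound_meta must contain columns: ",
                 paste(need_cpd, collapse = ", ")))
  }
  if (!setequal(cell_meta$cell_line, rownames(auc))) {
    abort("cell_meta$cell_line must match rownames(auc)")
  }
  if (!setequal(compound_meta$compound, colnames(auc))) {
    abort("compound_meta$compound must match colnames(auc)")
  }
  cell_meta <- cell_meta[match(rownames(auc), cell_meta$cell_line), ]
  compound_meta <- compound_meta[match(colnames(auc), compound_meta$compound), ]
  structure(
    list(auc = auc, cell_meta = cell_meta, compound_meta = compound_meta),
    class = "sensitivity_dataset"
  )
}

#' @export
print.sensitivity_dataset <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_dataset> %d cell lines x %d compounds (%.1f%% AUC missing)\n",
    nrow(x$auc), ncol(x$auc), 100 * mean(is.na(x$auc))
  ))
  cat(sprintf("  pediatric lines: %d; tumor types: %d; target pathways: %d\n",
              sum(x$cell_meta$pediatric), length(unique(x$cell_meta$tumor_type)),
              length(unique(x$compound_meta$target_pathway))))
  invisible(x)
}

#' Compound sets from dataset annotations
#'
#' Groups compounds by their annotated `target` or `target_pathway` into a
#' named set collection, analogous to gene sets, for use with
#' [permutation_test()] and [compound_set_enrichment()].
#'
#' @param dataset A [sensitivity_dataset()].
#' @param grouping `"target_pathway"` or `"target"`.
#' @return Named list of compound-identifier vectors.
#' @export
compound_sets <- function(dataset, grouping = c("target_pathway", "target")) {
  grouping <- match.arg(grouping)
  meta <- dataset$compound_meta
  split(meta$compound, meta[[grouping]])
}

#' Write / read a sensitivity dataset as TSV files
#'
#' Serializes the AUC matrix and both metadata tables to three TSV files
#' under a common prefix (`<prefix>_auc.tsv`, `<prefix>_cells.tsv`,
#' `<prefix>_compounds.tsv`); `read_sensitivity_dataset()` restores an
#' identical object.
#'
#' @param dataset A [sensitivity_dataset()].
#' @param prefix Path prefix for the three files.
#' @return `prefix`, invisibly (writer); the dataset (reader).
#' @export
write_sensitivity_dataset <- function(dataset, prefix) {
  auc_tbl <- tibble::as_tibble(dataset$auc, rownames = "cell_line")
  readr::write_tsv(auc_tbl, paste0(prefix, "_auc.tsv"))
  readr::write_tsv(dataset$cell_meta, paste0(prefix, "_cells.tsv"))
  readr::write_tsv(dataset$compound_meta, paste0(prefix, "_compounds.tsv"))
  invisible(prefix)
}

#' @rdname write_sensitivity_dataset
#' @export
read_sensitivity_dataset <- function(prefix) {
  auc_tbl <- readr::read_tsv(paste0(prefix, "_auc.tsv"),
                             show_col_types = FALSE, progress = FALSE)
  auc <- as.matrix(auc_tbl[-1])
  rownames(auc) <- auc_tbl$cell_line
  sensitivity_dataset(
    auc,
    readr::read_tsv(paste0(prefix, "_cells.tsv"),
                    show_col_types = FALSE, progress = FALSE),
    readr::read_tsv(paste0(prefix, "_compounds.tsv"),
                    show_col_types = FALSE, progress = FALSE)
  )
}
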