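#' Compound-set enrichment: pediatric vs adult sensitivity
#'
#' Tests whether compounds sharing a target or target pathway are
#' systematically more (or less) effective in pediatric than adult cell
#' lines. Per compound, AUC values are compared between the groups with an
#' empirical-Bayes moderated t-statistic ([moderated_t()] with a
#' group-indicator design); compounds are then ranked by t and compound
#' sets (from the dataset's annotations) are scored with
#' [permutation_test()].
#'
#' Sign convention: the tested coefficient is the pediatric indicator, so a
#' pathway whose compounds have lower AUC (more kill) in pediatric lines
#' gets a negative NES — negative NES means more sensitivity in pediatric
#' lines.
#'
#' @param dataset A [sensitivity_dataset()].
#' @param grouping `"target_pathway"` (default) or `"target"`.
#' @param n_perm,seed,min_size,weight Passed to [permutation_test()].
#' @param min_per_group Minimum non-missing AUC values per group for a
#'   compound to enter the ranking (default 3); compounds below it are
#'   dropped with a message.
#' @return An `enrichment_result` tibble, with the compound ranking in
#'   attribute `"ranking"`.
#' @export
compound_set_enrichment <- function(dataset,
                                    grouping = c("target_pathway", "target"),
                                    n_perm = 1000, seed = NULL, min_size = 5,
                                    weight = 1, min_per_group = 3) {
  grouping <- match.arg(grouping)
  grp <- dataset$cell_meta$pediatric
  if (sum(grp) < 3 || sum(!grp) < 3) {
    abort("both pediatric and adult groups must have >= 3 cell lines")
  }
  y <- t(dataset$auc)  # compounds x lines
  ok <- rowSums(!is.na(y[, grp, drop = FALSE])) >= min_per_group &
    rowSums(!is.na(y[, !grp, drop = FALSE])) >= min_per_group
  if (any(!ok)) {
    warn(paste0(sum(!ok), " compound(s) dropped: fewer than ", min_per_group,
                " AUC values in a group"))
    y <- y[ok, , drop = FALSE]
  }
  design <- model.matrix(~pediatric, data = dataset$cell_meta)
  mt <- moderated_t(y, design, "pediatricTRUE")
  ranking <- rank_features(mt)
  sets <- compound_sets(dataset, grouping)
  res <- permutation_test(ranking, sets, n_perm = n_perm, seed = seed,
                          min_size = min_size, weight = weight)
  attr(res, "ranking") <- ranking
  res
}

#' Gene-set enrichment against continuous drug sensitivity
#'
#' Identifies expression programs associated with sensitivity to one
#' compound: each gene is regressed on the compound's AUC (continuous)
#' adjusted for tumor type (categorical, when at least two types are
#' present), genes are ranked by the moderated t of the AUC coefficient,
#' and gene sets are scored with [permutation_test()].
#'
#' Sign convention: a negative t means higher expression goes with lower
#' AUC, i.e. greater sensitivity; gene sets enriched among sensitive-
#' associated genes therefore get negative NES.
#'
#' @param expression Numeric matrix, genes x cell lines (column names are
#'   cell-line identifiers).
#' @param dataset A [sensitivity_dataset()] providing the AUC and tumor
#'   types.
#' @param compound Compound identifier present in the dataset.
#' @param genesets Named list of gene sets (e.g. [read_gmt()]).
#' @param n_perm,seed,min_size,weight Passed to [permutation_test()].
#' @return An `enrichment_result` tibble, with the gene ranking in
#'   attribute `"ranking"`.
#' @export
biomarker_gsea <- function(expression, dataset, compound, genesets,
                           n_perm = 1000, seed = NULL, min_size = 5,
                           weight = 1) {
  if (!compound %in% colnames(dataset$auc)) {
    abort(paste0("compound absent from dataset: ", compound))
  }
  auc <- dataset$auc[, compound]
  lines <- intersect(colnames(expression), names(auc)[!is.na(auc)])
  if (length(lines) < 4) abort("too few cell lines with both expression and AUC")
  meta <- dataset$cell_meta[match(lines, dataset$cell_meta$cell_line), ]
  covars <- data.frame(auc = auc[lines])
  if (length(unique(meta$tumor_type)) >= 2) {
    covars$tumor_type <- factor(meta$tumor_type)
    design <- model.matrix(~ auc + tumor_type, data = covars)
  } else {
    design <- model.matrix(~auc, data = covars)
  }
  mt <- moderated_t(expression[, lines, drop = FALSE], design, "auc")
  ranking <- rank_features(mt)
  res <- permutation_test(ranking, genesets, n_perm = n_perm, seed = seed,
                          min_size = min_size, weight = weight)
  attr(res, "ranking") <- ranking
  res
}

#' Mutation-stratified drug sensitivity
#'
#' Convenience view of differential sensitivity with a binary covariate:
#' summarizes a compound's AUC by mutation status and tests the difference
#' with a two-sided Wilcoxon rank-sum test (exact where sample sizes
#' permit).
#'
#' @param dataset A [sensitivity_dataset()] whose `cell_meta` carries the
#'   logical mutation-flag column.
#' @param compound Compound identifier.
#' @param mutation_flag Name of the logical column in `cell_meta` (e.g.
#'   `"STAG2"`).
#' @param pediatric_only Restrict to pediatric cell lines?
#' @return One-row tibble: group sizes, medians, means and `p_value`.
#' @export
mutation_association <- function(dataset, compound, mutation_flag,
                                 pediatric_only = FALSE) {
  if (!compound %in% colnames(dataset$auc)) {
    abort(paste0("compound absent from dataset: ", compound))
  }
  if (!mutation_flag %in% names(dataset$cell_meta)) {
    abort(paste0("mutation flag absent from cell_meta: ", mutation_flag))
  }
  meta <- dataset$cell_meta
  auc <- dataset$auc[, compound]
  keep <- !is.na(auc) & !is.na(meta[[mutation_flag]])
  if (pediatric_only) keep <- keep & meta$pediatric
  auc <- auc[keep]
  mut <- meta[[mutation_flag]][keep]
  if (sum(mut) == 0 || sum(!mut) == 0) {
    abort("both mutation groups must be non-empty")
  }
  w <- wilcox.test(auc[mut], auc[!mut], alternative = "two.sided")
  tibble::tibble(
    compound = compound, mutation = mutation_flag,
    n_mutant = sum(mut), n_wildtype = sum(!mut),
    median_mutant = median(auc[mut]), median_wildtype = median(auc[!mut]),
    mean_mutant = mean(auc[mut]), mean_wildtype = mean(auc[!mut]),
    p_value = w$p.value
  )
}
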