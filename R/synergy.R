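#' Anchored combination viability grid
#'
#' Container for one cell line's combination screen between an anchor
#' compound (rows) and a library compound (columns): the observed viability
#' grid at every dose pair, plus the monotherapy margins needed for Bliss
#' scoring. A 10x10 validation matrix and a 1x6 anchored library series are
#' both represented this way (the anchored case has a single anchor dose).
#'
#' @param viability Numeric matrix of viability fractions,
#'   `length(dose_a) x length(dose_b)`.
#' @param dose_a,dose_b Strictly increasing dose vectors (nM) for the
#'   anchor and library compound.
#' @param mono_a,mono_b Monotherapy viability of each compound alone at
#'   `dose_a` / `dose_b` (`NA` marks a missing margin; cells depending on it
#'   are excluded from averages).
#' @param cell_line,compound_a,compound_b Identifiers.
#' @return A `combo_matrix` object.
#' @export
combination_matrix <- function(viability, dose_a, dose_b, mono_a, mono_b,
                               cell_line = NA_character_,
                               compound_a = NA_character_,
                               compound_b = NA_character_) {
  viability <- as.matrix(viability)
  if (nrow(viability) != length(dose_a) || ncol(viability) != length(dose_b)) {
    abort("viability grid dimensions must match dose vectors")
  }
  if (length(mono_a) != length(dose_a) || length(mono_b) != length(dose_b)) {
    abort("monotherapy margins must align with dose vectors")
  }
  if (any(diff(dose_a) <= 0) || any(diff(dose_b) <= 0)) {
    abort("dose vectors must be strictly increasing")
  }
  if (any(c(dose_a, dose_b) <= 0)) {
    abort("combination doses must be > 0 (margins are carried separately)")
  }
  structure(
    list(viability = viability, dose_a = dose_a, dose_b = dose_b,
         mono_a = mono_a, mono_b = mono_b, cell_line = cell_line,
         compound_a = compound_a, compound_b = compound_b),
    class = "combo_matrix"
  )
}

#' @export
print.combo_matrix <- function(x, ...) {
  cat(sprintf("<combo_matrix> %s: %s (%d doses) x %s (%d doses)\n",
              x$cell_line, x$compound_a, length(x$dose_a),
              x$compound_b, length(x$dose_b)))
  invisible(x)
}

# Inhibition fraction from viability; Bliss operates on probabilities,
# so inhibition is clipped into [0, 1] (viability itself is not clipped
# elsewhere in the package).
inhibition <- function(viability) clip(1 - viability, 0, 1)

#' Bliss-independence expected inhibition
#'
#' Expected combined inhibition of two independently acting drugs:
#' `fa + fb - fa * fb`. Symmetric in its arguments; an inhibition of 1 by
#' either drug is absorbing.
#'
#' @param fa,fb Inhibition fractions in `[0, 1]` (vectorized).
#' @return Expected combined inhibition fraction.
#' @export
bliss_expected <- function(fa, fb) {
  if (any(fa < 0 | fa > 1 | fb < 0 | fb > 1, na.rm = TRUE)) {
    abort("bliss_expected requires inhibition fractions in [0, 1]")
  }
  fa + fb - fa * fb
}

#' Bliss excess over a combination grid
#'
#' For every dose pair (both doses > 0), the observed combined inhibition
#' minus the Bliss-independence expectation computed from the monotherapy
#' margins. Positive excess indicates synergy. Cells whose margins are
#' missing are `NA` and excluded from all downstream averages.
#'
#' @param m A [combination_matrix()].
#' @return Matrix of excess scores aligned with `m$viability`.
#' @export
bliss_excess_matrix <- function(m) {
  fa <- inhibition(m$mono_a)
  fb <- inhibition(m$mono_b)
  expected <- outer(fa, fb, bliss_expected)
  excess <- inhibition(m$viability) - expected
  dimnames(excess) <- dimnames(m$viability)
  excess
}

#' Average Bliss synergy score
#'
#' Arithmetic mean of the Bliss excess over all defined combination cells.
#' Zero marks independence; the score is the screen-level "average synergy
#' score" entering hit selection.
#'
#' @param excess Excess matrix from [bliss_excess_matrix()].
#' @return Mean excess, or `NA` when no cell is defined.
#' @export
average_bliss <- function(excess) {
  vals <- excess[!is.na(excess)]
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

#' Fold change in maximum effect at the top library dose
#'
#' `Emax` is the inhibition (clipped to `[0, 1]`) at the highest library
#' dose; the fold change is `Emax_combination / Emax_monotherapy`. A
#' monotherapy Emax of 0 with any combination effect yields `Inf` (maximal
#' evidence of improvement, satisfying any finite threshold); 0/0 is
#' defined as 1 (no change).
#'
#' @param mono,combo Tibbles with `dose` and `viability` for the library
#'   compound alone and in combination; both must include the top library
#'   dose.
#' @return Fold change (>= 0, possibly `Inf`).
#' @export
delta_emax <- function(mono, combo) {
  top <- max(mono$dose)
  v_mono <- mono$viability[mono$dose == top]
  v_combo <- combo$viability[combo$dose == top]
  if (length(v_mono) != 1 || length(v_combo) != 1 ||
      !is.finite(v_mono) || !is.finite(v_combo)) {
    abort("delta_emax: both series must measure the top library dose exactly once")
  }
  e_mono <- inhibition(v_mono)
  e_combo <- inhibition(v_combo)
  if (e_mono == 0) {
    if (e_combo == 0) return(1)
    return(Inf)
  }
  e_combo / e_mono
}

#' Fold change in IC50 between monotherapy and combination
#'
#' Returns `IC50_mono / IC50_combo`, so values above 1 mean the combination
#' lowers the IC50 (improvement). Censored IC50s enter as their censoring
#' bound — a conservative substitution that keeps the fold change defined.
#' When both are censored at the same bound the fold change is reported as
#' 1 with attribute `both_censored = TRUE`.
#'
#' @param mono_fit,combo_fit `drfit` objects from [fit_4pl()], or lists
#'   with `value` and `censored` as from [absolute_ic50()].
#' @return Fold change (> 0, possibly `Inf`).
#' @export
delta_ic50 <- function(mono_fit, combo_fit) {
  a <- as_ic50(mono_fit)
  b <- as_ic50(combo_fit)
  if (a$censored != "none" && a$censored == b$censored) {
    return(structure(1, both_censored = TRUE))
  }
  if (b$value == 0) return(Inf)
  a$value / b$value
}

as_ic50 <- function(x) {
  if (inherits(x, "drfit")) return(list(value = x$ic50, censored = x$ic50_censored))
  if (is.list(x) && all(c("value", "censored") %in% names(x))) return(x)
  if (is.numeric(x) && length(x) == 1) return(list(value = x, censored = "none"))
  abort("delta_ic50 expects drfit objects, absolute_ic50() lists, or numbers")
}

#' Average synergy metrics across anchor concentrations
#'
#' Combination outcomes are computed at up to three anchor doses of the
#' anchor drug (its per-cell-line IC15, IC25 and IC50); the screen-level
#' metrics are the arithmetic means over the anchors at which each metric
#' is defined. `Inf` fold changes propagate (a mean involving `Inf` is
#' `Inf`).
#'
#' @param per_anchor Tibble with one row per anchor and columns
#'   `delta_emax`, `delta_ic50`, `bliss_avg` (an `anchor` label column is
#'   carried through if present).
#' @return One-row tibble with the averaged metrics and `n_anchors`.
#' @export
anchored_metrics <- function(per_anchor) {
  if (nrow(per_anchor) == 0) abort("anchored_metrics requires >= 1 anchor")
  mean_defined <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    mean(x)
  }
  tibble::tibble(
    delta_emax = mean_defined(per_anchor$delta_emax),
    delta_ic50 = mean_defined(per_anchor$delta_ic50),
    bliss_avg = mean_defined(per_anchor$bliss_avg),
    n_anchors = nrow(per_anchor)
  )
}

#' Rule-based synergy hit selection
#'
#' A combination is a hit when its anchor-averaged fold change in Emax or
#' IC50 exceeds 5, or its average Bliss score exceeds 0 — all strict
#' inequalities, so values exactly at a threshold are not hits. Undefined
#' metrics never satisfy their criterion.
#'
#' @param metrics Tibble (or one-row list) with columns `delta_emax`,
#'   `delta_ic50`, `bliss_avg`.
#' @param fc_threshold Fold-change threshold (default 5).
#' @param bliss_threshold Average-Bliss threshold (default 0).
#' @return Logical vector, one flag per row.
#' @export
select_hits <- function(metrics, fc_threshold = 5, bliss_threshold = 0) {
  gt <- function(x, thr) !is.na(x) & x > thr
  gt(metrics$delta_emax, fc_threshold) |
    gt(metrics$delta_ic50, fc_threshold) |
    gt(metrics$bliss_avg, bliss_threshold)
}

#' Maximum effective synergy
#'
#' The highest Bliss excess among combination cells whose observed
#' viability is below 50% — synergy that coincides with a therapeutically
#' meaningful effect size, not just a relative improvement at ineffective
#' doses.
#'
#' @param m A [combination_matrix()].
#' @param excess Excess matrix from [bliss_excess_matrix()] (recomputed
#'   when omitted).
#' @param viability_cutoff Qualifying viability ceiling (default 0.5,
#'   strict).
#' @return Maximum qualifying excess, or `NA` when no cell qualifies.
#' @export
max_effective_synergy <- function(m, excess = NULL, viability_cutoff = 0.5) {
  if (is.null(excess)) excess <- bliss_excess_matrix(m)
  stopifnot(all(dim(excess) == dim(m$viability)))
  ok <- !is.na(excess) & !is.na(m$viability) & m$viability < viability_cutoff
  if (!any(ok)) return(NA_real_)
  max(excess[ok])
}

#' Library compounds synergistic in every screened cell line
#'
#' Intersects per-cell-line hit calls: a compound is returned only when it
#' was screened in, and flagged as a hit in, every cell line in the table.
#' Compounds left unscreened in any line (`NA` hit flag or absent row) are
#' excluded from the intersection domain rather than counted as misses.
#'
#' @param hits Tibble with columns `cell_line`, `compound` and logical
#'   `is_hit` (`NA` = not screened).
#' @return Character vector of compounds, sorted.
#' @export
cross_entity_overlap <- function(hits) {
  stopifnot(all(c("cell_line", "compound", "is_hit") %in% names(hits)))
  lines <- unique(hits$cell_line)
  if (length(lines) < 2) abort("cross_entity_overlap requires >= 2 cell lines")
  if (length(unique(hits$compound)) == 0) abort("empty compound library")
  tab <- hits |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(
      screened_everywhere = sum(!is.na(.data$is_hit)) == length(lines),
      hit_everywhere = all(.data$is_hit %in% TRUE),
      .groups = "drop"
    )
  sort(tab$compound[tab$screened_everywhere & tab$hit_everywhere])
}

#' Score an anchored combination library screen
#'
#' End-to-end synergy scoring for one cell line of an anchored screen: for
#' each library compound, fits the monotherapy dose-response, then per
#' anchor dose fits the combination series (library dose on the x-axis,
#' anchor held fixed, viability normalized to untreated control), and
#' computes the three outcome metrics — fold change in Emax at the top
#' library dose, fold change in IC50, and average Bliss excess over the
#' combination cells. Metrics are averaged across anchors and hit flags
#' assigned by [select_hits()].
#'
#' @param screen A list with tibbles `mono` (`cell_line, compound, dose,
#'   viability`), `combo` (`cell_line, anchor, anchor_dose, compound, dose,
#'   viability`) and `anchor_mono` (`cell_line, anchor, anchor_dose,
#'   viability`), e.g. from [gen_anchored_library_screen()] or assembled
#'   from [normalize_viability()] output.
#' @param fc_threshold,bliss_threshold Passed to [select_hits()].
#' @param ic50_normalize Normalization of the combination curve fitted for
#'   the IC50 fold change: `"untreated"` (default) fits the viability as
#'   measured against untreated control; `"anchor"` first divides by the
#'   anchor-alone viability, so the curve isolates the library drug's
#'   contribution on top of the anchor. Under the untreated convention the
#'   anchor alone depresses the whole curve, which inflates IC50 fold
#'   changes even without synergy; the Emax and Bliss metrics are
#'   unaffected by this choice.
#' @return Tibble with one row per (cell_line, compound): averaged
#'   `delta_emax`, `delta_ic50`, `bliss_avg`, `is_hit`, and a `per_anchor`
#'   list-column of per-anchor metrics.
#' @export
score_anchored_screen <- function(screen, fc_threshold = 5, bliss_threshold = 0,
                                  ic50_normalize = c("untreated", "anchor")) {
  ic50_normalize <- match.arg(ic50_normalize)
  mono <- screen$mono
  combo <- screen$combo
  anchor_mono <- screen$anchor_mono

  res <- mono |>
    dplyr::group_by(.data$cell_line, .data$compound) |>
    dplyr::group_modify(function(mono_pts, key) {
      mono_fit <- fit_4pl(mono_pts)
      cmb <- combo[combo$cell_line == key$cell_line &
                     combo$compound == key$compound, , drop = FALSE]
      anc <- anchor_mono[anchor_mono$cell_line == key$cell_line, , drop = FALSE]
      per_anchor <- purrr::map_dfr(split(cmb, cmb$anchor), function(ca) {
        fa_viab <- anc$viability[anc$anchor == ca$anchor[1]]
        m <- combination_matrix(
          viability = matrix(ca$viability[order(ca$dose)], nrow = 1),
          dose_a = ca$anchor_dose[1],
          dose_b = sort(ca$dose),
          mono_a = fa_viab,
          mono_b = mono_pts$viability[order(mono_pts$dose)][
            match(sort(ca$dose), sort(mono_pts$dose))],
          cell_line = key$cell_line, compound_b = key$compound
        )
        fit_pts <- ca[c("dose", "viability")]
        if (ic50_normalize == "anchor") {
          fit_pts$viability <- fit_pts$viability / fa_viab
        }
        combo_fit <- fit_4pl(fit_pts)
        tibble::tibble(
          anchor = ca$anchor[1],
          delta_emax = delta_emax(mono_pts, ca),
          delta_ic50 = as.numeric(delta_ic50(mono_fit, combo_fit)),
          bliss_avg = average_bliss(bliss_excess_matrix(m))
        )
      })
      avg <- anchored_metrics(per_anchor)
      avg$mono_ic50_nM <- mono_fit$ic50
      avg$mono_ic50_censored <- mono_fit$ic50_censored
      avg$per_anchor <- list(per_anchor)
      avg
    }) |>
    dplyr::ungroup()
  res$is_hit <- select_hits(res, fc_threshold, bliss_threshold)
  res
}

#' Bliss excess heatmap for a combination matrix
#'
#' @param m A [combination_matrix()].
#' @param excess Optional precomputed excess matrix.
#' @return A ggplot: dose grid tiles colored by Bliss excess (blue =
#'   antagonism, red = synergy).
#' @export
plot_bliss_matrix <- function(m, excess = NULL) {
  if (is.null(excess)) excess <- bliss_excess_matrix(m)
  df <- expand.grid(dose_a = m$dose_a, dose_b = m$dose_b)
  df$excess <- as.vector(excess)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(signif(.data$dose_b, 3)),
                                   y = factor(signif(.data$dose_a, 3)),
                                   fill = .data$excess)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0) +
    ggplot2::labs(x = paste0(m$compound_b, " (nM)"),
                  y = paste0(m$compound_a, " (nM)"), fill = "Bliss excess")
}
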