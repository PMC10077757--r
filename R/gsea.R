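#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks down a ranked feature list accumulating a running sum: at each set
#' member ("hit") the sum increases by that feature's weight
#' `|t|^p / sum_set |t|^p`, at each non-member it decreases by
#' `1 / (N - set size)`. The enrichment score is the signed extremum of the
#' running sum: positive when the set concentrates at the top of the
#' ranking, negative at the bottom, and bounded in `[-1, 1]`. With
#' `weight = 0` every hit counts equally (classic KS); the default
#' `weight = 1` is the standard GSEA weighting.
#'
#' If every hit weight is zero (all member statistics exactly 0), hits fall
#' back to equal weights.
#'
#' @param ranking Named numeric vector ordered as produced by
#'   [rank_features()].
#' @param set Character vector of member identifiers.
#' @param weight KS weighting exponent `p` (default 1).
#' @return List with `es`, the full `running` sum, the `leading_edge`
#'   members (those at or beyond the extremum, on its side), and `size`
#'   (members present in the ranking). Returns `es = NA` when no member is
#'   present.
#' @export
enrichment_score <- function(ranking, set, weight = 1) {
  N <- length(ranking)
  hit <- names(ranking) %in% set
  m <- sum(hit)
  if (m == 0) {
    return(list(es = NA_real_, running = NULL, leading_edge = character(),
                size = 0L))
  }
  w <- abs(ranking[hit])^weight
  sw <- sum(w)
  inc <- if (sw == 0) rep(1 / m, m) else w / sw
  steps <- numeric(N)
  steps[hit] <- inc
  if (m < N) steps[!hit] <- -1 / (N - m)
  running <- cumsum(steps)
  imax <- which.max(running)
  imin <- which.min(running)
  # Exact ties between the positive and negative extremum (common in the
  # unweighted case) resolve to the positive one; the 1e-12 slack keeps the
  # choice stable against floating-point summation order.
  es <- if (running[imax] >= -running[imin] - 1e-12) running[imax] else running[imin]
  leading <- if (es >= 0) {
    names(ranking)[seq_len(imax)][hit[seq_len(imax)]]
  } else {
    names(ranking)[imin:N][hit[imin:N]]
  }
  list(es = unname(es), running = unname(running), leading_edge = leading,
       size = m)
}

# Enrichment score from hit positions only: O(set size) per evaluation,
# used for permutation nulls. `a` is |t|^p over the full ranking in rank
# order. The running-sum extrema can only occur at a hit (maximum) or just
# before a hit / at the walk's endpoints (minimum).
es_from_positions <- function(pos, a, N) {
  pos <- sort.int(pos)
  m <- length(pos)
  w <- a[pos]
  sw <- sum(w)
  W <- if (sw == 0) seq_len(m) / m else cumsum(w) / sw
  miss <- (pos - seq_len(m)) / (N - m)
  at_hit <- W - miss
  before_hit <- c(0, W[-m]) - miss
  mx <- max(at_hit, 0)
  mn <- min(before_hit, 0)
  if (mx >= -mn - 1e-12) mx else mn
}

#' Permutation-based set enrichment with normalized scores
#'
#' Computes the weighted-KS enrichment score for every set, then builds a
#' null distribution per set size by drawing random member sets of the same
#' size from the ranked universe. The normalized enrichment score divides
#' each observed score by the mean magnitude of same-sign null scores; the
#' permutation p-value is `(1 + #{same-sign nulls at least as extreme}) /
#' (1 + #{same-sign nulls})`. p-values are adjusted across sets by
#' Benjamini-Hochberg.
#'
#' @param ranking Named numeric vector from [rank_features()].
#' @param sets Named list of member vectors (e.g. [read_gmt()] or
#'   [compound_sets()]).
#' @param n_perm Number of null draws per set size (>= 100).
#' @param seed Optional integer; given the same seed the result is
#'   reproducible and the caller's RNG stream is left untouched.
#' @param min_size Minimum number of members present in the ranking
#'   (default 5, the conventional floor for pathway-level sets).
#' @param weight KS weighting exponent (default 1).
#' @return Tibble of class `enrichment_result`: `set`, `es`, `nes`,
#'   `pval`, `padj`, `size`, `leading_edge` (list-column).
#' @export
permutation_test <- function(ranking, sets, n_perm = 1000, seed = NULL,
                             min_size = 5, weight = 1) {
  if (n_perm < 100) abort("n_perm must be >= 100")
  N <- length(ranking)
  present <- lapply(sets, function(s) intersect(s, names(ranking)))
  sizes <- vapply(present, length, 1L)
  keep <- sizes >= min_size & sizes < N
  if (!any(keep)) {
    abort(paste0("no set passes the min_size filter (", min_size, ")"))
  }
  inform(paste0(sum(!keep), " of ", length(sets),
                " set(s) below min_size or outside the ranking; ",
                sum(keep), " tested"))
  present <- present[keep]
  sizes <- sizes[keep]

  a <- abs(ranking)^weight
  run <- function() {
    null_by_size <- lapply(
      setNames(unique(sizes), unique(sizes)),
      function(m) {
        vapply(seq_len(n_perm),
               function(i) es_from_positions(sample.int(N, m), a, N),
               numeric(1))
      }
    )
    purrr::map_dfr(names(present), function(nm) {
      sc <- enrichment_score(ranking, present[[nm]], weight = weight)
      null_es <- null_by_size[[as.character(sc$size)]]
      if (sc$es == 0) {
        return(tibble::tibble(set = nm, es = 0, nes = 0, pval = 1,
                              size = sc$size,
                              leading_edge = list(sc$leading_edge)))
      }
      same <- null_es[sign(null_es) == sign(sc$es)]
      if (length(same) == 0) {
        warn(paste0("no same-sign null scores for set '", nm,
                    "'; p set to 1"))
        nes <- NA_real_
        pval <- 1
      } else {
        nes <- sc$es / mean(abs(same))
        pval <- (1 + sum(abs(same) >= abs(sc$es))) / (1 + length(same))
      }
      tibble::tibble(set = nm, es = sc$es, nes = nes, pval = pval,
                     size = sc$size, leading_edge = list(sc$leading_edge))
    })
  }
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  res$padj <- bh_adjust(res$pval)
  res <- res[order(res$pval, -abs(res$nes)), ]
  res <- res[c("set", "es", "nes", "pval", "padj", "size", "leading_edge")]
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment across a family of tests, after
#' validating the inputs are proper p-values.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1)) {
    abort("bh_adjust requires p-values in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' @export
autoplot.enrichment_result <- function(object, alpha = 0.05, ...) {
  df <- as.data.frame(object[c("set", "nes", "padj", "size")])
  df$set <- factor(df$set, levels = df$set[order(df$nes)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nes, y = .data$set,
                                   size = .data$size,
                                   color = -log10(.data$padj))) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "normalized enrichment score", y = NULL,
                  color = "-log10 padj", size = "set size")
}
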