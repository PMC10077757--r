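#' Empirical-Bayes moderated t-statistics
#'
#' Fits per-feature ordinary least squares for a coefficient of interest
#' over an arbitrary design matrix, then shrinks the residual variances
#' toward a pooled prior estimated by method of moments on the
#' log-variances (the classic empirical-Bayes scheme for microarray-style
#' linear models). The moderated variance is
#' `s2_post = (d0 * s0^2 + d * s^2) / (d0 + d)` with prior df `d0` and
#' prior variance `s0^2`; the moderated t divides each coefficient by its
#' standard error rescaled with `s2_post`, on `d + d0` degrees of freedom.
#' With a single feature (or `d0 = 0`) this reduces exactly to the
#' ordinary t-statistic.
#'
#' Features with missing responses are fitted on their complete cases;
#' features left with zero residual degrees of freedom are dropped with a
#' warning.
#'
#' @param responses Numeric matrix, features x samples (rownames identify
#'   features). For drug-sensitivity contrasts the features are compounds
#'   and the values AUC fractions; for biomarker analyses the features are
#'   genes and the values expression.
#' @param design Numeric design matrix, samples x coefficients (e.g. from
#'   [stats::model.matrix()]); must be full rank.
#' @param coef Name (or index) of the coefficient of interest.
#' @return A `modt` object; `tidy()` gives the per-feature table
#'   (`feature`, `estimate`, `s2`, `df`, `s2_post`, `t`, `df_total`,
#'   `p_value`), `glance()` the prior df `d0` and prior variance `s02`.
#' @export
moderated_t <- function(responses, design, coef) {
  responses <- as.matrix(responses)
  design <- as.matrix(design)
  n <- ncol(responses)
  if (nrow(design) != n) abort("design rows must match response columns")
  p <- ncol(design)
  if (n <= p) abort("more design columns than samples: zero residual df")
  qr_x <- qr(design)
  if (qr_x$rank < p) {
    bad <- colnames(design)[qr_x$pivot[(qr_x$rank + 1):p]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (is.numeric(coef)) coef <- colnames(design)[coef]
  if (!coef %in% colnames(design)) {
    abort(paste0("coefficient not in design: ", coef))
  }
  j <- match(coef, colnames(design))
  feats <- rownames(responses) %||% as.character(seq_len(nrow(responses)))

  complete <- !apply(responses, 1, anyNA)
  est <- matrix(NA_real_, nrow(responses), 4,
                dimnames = list(feats, c("estimate", "s2", "df", "se_unscaled")))

  if (any(complete)) {
    xtx_inv <- chol2inv(chol(crossprod(design)))
    bmat <- responses[complete, , drop = FALSE] %*% design %*% xtx_inv
    resid <- responses[complete, , drop = FALSE] - bmat %*% t(design)
    est[complete, "estimate"] <- bmat[, j]
    est[complete, "s2"] <- rowSums(resid^2) / (n - p)
    est[complete, "df"] <- n - p
    est[complete, "se_unscaled"] <- sqrt(xtx_inv[j, j])
  }
  for (i in which(!complete)) {
    ok <- is.finite(responses[i, ])
    if (sum(ok) <= p) next  # dropped below
    xi <- design[ok, , drop = FALSE]
    if (qr(xi)$rank < p) next
    xtx_inv <- chol2inv(chol(crossprod(xi)))
    bi <- drop(xtx_inv %*% crossprod(xi, responses[i, ok]))
    ri <- responses[i, ok] - drop(xi %*% bi)
    est[i, ] <- c(bi[j], sum(ri^2) / (sum(ok) - p), sum(ok) - p,
                  sqrt(xtx_inv[j, j]))
  }
  dropped <- which(is.na(est[, "df"]))
  if (length(dropped) > 0) {
    warn(paste0(length(dropped),
                " feature(s) dropped: zero residual df after missing values"))
    est <- est[-dropped, , drop = FALSE]
    feats <- feats[-dropped]
  }
  if (nrow(est) == 0) abort("no feature has positive residual df")

  s2 <- est[, "s2"]
  d <- est[, "df"]
  hyper <- fit_log_variance_prior(s2, d)
  d0 <- hyper$d0
  s02 <- hyper$s02
  s2_post <- if (is.infinite(d0)) {
    rep(s02, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  tstat <- est[, "estimate"] / (est[, "se_unscaled"] * sqrt(s2_post))
  df_total <- d + d0
  tab <- tibble::tibble(
    feature = feats,
    estimate = unname(est[, "estimate"]),
    s2 = unname(s2),
    df = unname(d),
    s2_post = unname(s2_post),
    t = unname(tstat),
    df_total = unname(df_total),
    p_value = 2 * pt(-abs(unname(tstat)), df = unname(df_total))
  )
  structure(list(table = tab, d0 = d0, s02 = s02, coef = coef),
            class = "modt")
}

# Method-of-moments fit of a scaled inverse-chisq prior to the sample
# variances, on the log scale (Smyth-style). Returns d0 (possibly Inf,
# possibly 0 when moderation is impossible) and the prior variance s02.
fit_log_variance_prior <- function(s2, d) {
  usable <- s2 > 0 & d > 0
  if (sum(usable) < 2) {
    return(list(d0 = 0, s02 = NA_real_))  # no moderation possible
  }
  z <- log(s2[usable])
  e <- z - digamma(d[usable] / 2) + log(d[usable] / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - mean(trigamma(d[usable] / 2))
  if (!is.finite(evar) || evar <= 0) {
    # No excess dispersion beyond sampling noise: variances are exchangeable
    # and the pooled mean variance is the natural common value.
    return(list(d0 = Inf, s02 = mean(s2[usable])))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton inversion of the trigamma function.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

#' @export
tidy.modt <- function(x, ...) x$table

#' @export
glance.modt <- function(x, ...) {
  tibble::tibble(d0 = x$d0, s02 = x$s02, n_features = nrow(x$table),
                 coef = x$coef)
}

#' @export
print.modt <- function(x, ...) {
  cat(sprintf("<modt> %d features; coefficient '%s'; prior df %.3g, prior var %.3g\n",
              nrow(x$table), x$coef, x$d0, x$s02))
  invisible(x)
}

#' Rank features by moderated t-statistic
#'
#' Orders features by descending t, breaking ties lexicographically on the
#' feature identifier so the ranking is deterministic. Features with
#' non-finite t are dropped with a warning.
#'
#' @param stats A `modt` object from [moderated_t()], or a named numeric
#'   vector of statistics.
#' @return Named numeric vector of statistics, ordered for enrichment.
#' @export
rank_features <- function(stats) {
  if (inherits(stats, "modt")) {
    v <- setNames(stats$table$t, stats$table$feature)
  } else {
    v <- stats
  }
  if (is.null(names(v))) abort("rank_features requires named statistics")
  bad <- !is.finite(v)
  if (any(bad)) {
    warn(paste0(sum(bad), " feature(s) with non-finite statistic dropped: ",
                paste(head(names(v)[bad], 5), collapse = ", ")))
    v <- v[!bad]
  }
  if (length(v) < 2) abort("rank_features requires >= 2 finite statistics")
  v[order(-v, names(v), method = "radix")]
}
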