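#' Four-parameter logistic viability model
#'
#' Evaluates `V(c) = einf + (e0 - einf) / (1 + (c / ec50)^hill)` at doses
#' `c` (nM). At `c = 0` the model returns `e0`. With `hill > 0` and
#' `e0 > einf` the curve decreases from the untreated baseline `e0` to the
#' infinite-dose plateau `einf`, with inflection at `ec50`.
#'
#' @param dose Dose vector, nM, `>= 0`.
#' @param e0,einf,ec50,hill Model parameters (viability fractions for
#'   `e0`/`einf`; `ec50` in nM; dimensionless `hill > 0`).
#' @return Predicted viability fractions.
#' @export
fourpl <- function(dose, e0, einf, ec50, hill) {
  n <- max(length(dose), length(e0), length(einf), length(ec50), length(hill))
  dose <- rep_len(dose, n)
  e0 <- rep_len(e0, n)
  v <- rep_len(einf, n) + (e0 - rep_len(einf, n)) /
    (1 + (dose / rep_len(ec50, n))^rep_len(hill, n))
  v[dose <= 0] <- e0[dose <= 0]
  unname(v)
}

# Parameter bounds keeping 6-point fits identifiable:
# e0 in [0.5, 1.5], einf in [-0.1, 1.2], hill in [0.1, 10],
# log10(ec50) in [log10(cmin) - 2, log10(cmax) + 2].
fit_bounds <- function(log_cmin, log_cmax) {
  list(
    lower = c(theta = log_cmin - 2, hill = 0.1, e0 = 0.5, einf = -0.1),
    upper = c(theta = log_cmax + 2, hill = 10, e0 = 1.5, einf = 1.2)
  )
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the [fourpl()] model in log10-dose space for one
#' cell line x compound series, with a fixed deterministic multi-start grid
#' (5 starting log-EC50 values spanning the tested range crossed with 3
#' starting Hill slopes; best sum of squared errors wins, ties broken by
#' smaller Hill slope then smaller EC50). Derived metrics are the absolute
#' IC50 (dose at which the fitted curve crosses 50% viability, censored at
#' the tested range) and the normalized AUC over the tested log-dose window.
#'
#' If the optimizer fails to converge from every start, model-free fallback
#' metrics are reported instead: IC50 by log-linear interpolation between
#' the bracketing observed points and AUC by the trapezoid rule on the
#' observed points; the fit is flagged `converged = FALSE`.
#'
#' @param points Tibble with columns `dose` (nM) and `viability` (fraction
#'   of control); at least 4 distinct doses > 0. A dose-0 row, when present,
#'   informs the `e0` baseline.
#' @param quadrature_n Number of quadrature nodes for [curve_auc()].
#' @return A `drfit` object: list with elements `e0`, `einf`, `ec50`,
#'   `hill`, `converged`, `degenerate`, `ic50`, `ic50_censored` (`"none"`,
#'   `">cmax"` or `"<cmin"`), `auc`, `dose_range`, `sse`, `data`.
#' @export
#' @examples
#' pts <- tibble::tibble(dose = c(0.1, 1, 10, 100, 1000, 10000),
#'                       viability = fourpl(c(0.1, 1, 10, 100, 1000, 10000),
#'                                          1, 0, 10, 1))
#' fit <- fit_4pl(pts)
#' glance(fit)
fit_4pl <- function(points, quadrature_n = 1025) {
  stopifnot(all(c("dose", "viability") %in% names(points)))
  pts <- points[is.finite(points$dose) & is.finite(points$viability), ]
  doses_pos <- sort(unique(pts$dose[pts$dose > 0]))
  if (length(doses_pos) < 4) {
    abort("insufficient data: fit_4pl requires >= 4 distinct doses > 0")
  }
  cmin <- doses_pos[1]
  cmax <- doses_pos[length(doses_pos)]
  v <- pts$viability
  d <- pts$dose

  if (length(unique(v)) == 1L) {
    # Flat data: slope unidentifiable, flag and report the constant level.
    fit <- new_drfit(
      e0 = v[1], einf = v[1], ec50 = sqrt(cmin * cmax), hill = NA_real_,
      converged = FALSE, degenerate = TRUE, dose_range = c(cmin, cmax),
      sse = 0, data = pts
    )
    fit$auc <- clip(v[1], 0, 1)
    ic <- absolute_ic50(fit)
    fit$ic50 <- ic$value
    fit$ic50_censored <- ic$censored
    return(fit)
  }

  lx <- log10(c(cmin, cmax))
  b <- fit_bounds(lx[1], lx[2])
  pos <- d > 0
  xlog <- log10(d[pos])
  ln10 <- log(10)
  # par = (theta = log10 ec50, hill, e0, einf); model in log-dose space is
  # pred = einf + (e0 - einf) / (1 + 10^(hill * (x - theta))).
  sse_fun <- function(par) {
    u <- 10^(par[2] * (xlog - par[1]))
    pred <- numeric(length(d))
    pred[pos] <- par[4] + (par[3] - par[4]) / (1 + u)
    pred[!pos] <- par[3]
    sum((v - pred)^2)
  }
  sse_grad <- function(par) {
    u <- 10^(par[2] * (xlog - par[1]))
    inv <- 1 / (1 + u)
    pred <- numeric(length(d))
    pred[pos] <- par[4] + (par[3] - par[4]) * inv
    pred[!pos] <- par[3]
    r <- v - pred
    rp <- r[pos]
    span <- par[3] - par[4]
    common <- span * u * inv^2 * ln10
    g_theta <- -2 * sum(rp * common * par[2])
    g_hill <- -2 * sum(rp * -common * (xlog - par[1]))
    g_e0 <- -2 * (sum(rp * inv) + sum(r[!pos]))
    g_einf <- -2 * sum(rp * (1 - inv))
    c(g_theta, g_hill, g_e0, g_einf)
  }
  e0_start <- clip(mean(v[d == cmin]), 0.5, 1.5)
  einf_start <- clip(mean(v[d == cmax]), -0.1, 1.2)
  theta_grid <- seq(lx[1], lx[2], length.out = 5)
  hill_grid <- c(0.5, 1, 3)

  best <- NULL
  for (th in theta_grid) {
    for (h in hill_grid) {
      res <- tryCatch(
        stats::optim(c(th, h, e0_start, einf_start), sse_fun, gr = sse_grad,
                     method = "L-BFGS-B", lower = b$lower, upper = b$upper),
        error = function(e) NULL
      )
      if (is.null(res) || !is.finite(res$value)) next
      cand <- list(par = res$par, sse = res$value, ok = res$convergence == 0)
      if (is.null(best) || better_fit(cand, best)) best <- cand
    }
  }
  if (!is.null(best) && best$ok) {
    # High-precision polish from the winning start.
    for (k in 1:2) {
      pol <- tryCatch(
        stats::optim(best$par, sse_fun, gr = sse_grad, method = "L-BFGS-B",
                     lower = b$lower, upper = b$upper,
                     control = list(factr = 1, pgtol = 1e-14, maxit = 1000)),
        error = function(e) NULL
      )
      if (!is.null(pol) && is.finite(pol$value) && pol$value <= best$sse) {
        best$par <- pol$par
        best$sse <- pol$value
      }
    }
  }

  if (is.null(best) || !best$ok) {
    return(fallback_fit(pts, cmin, cmax, best))
  }
  p <- best$par
  fit <- new_drfit(
    e0 = p[3], einf = p[4], ec50 = 10^p[1], hill = p[2],
    converged = TRUE, degenerate = FALSE, dose_range = c(cmin, cmax),
    sse = best$sse, data = pts
  )
  fit$auc <- curve_auc(fit, n = quadrature_n)
  ic <- absolute_ic50(fit)
  fit$ic50 <- ic$value
  fit$ic50_censored <- ic$censored
  fit
}

# SSE comparison with deterministic tie-breaking: smaller hill, then
# smaller ec50, decide among numerically equal optima.
better_fit <- function(cand, best, tol = 1e-10) {
  if (cand$sse < best$sse - tol) return(TRUE)
  if (cand$sse > best$sse + tol) return(FALSE)
  if (cand$par[2] != best$par[2]) return(cand$par[2] < best$par[2])
  cand$par[1] < best$par[1]
}

new_drfit <- function(e0, einf, ec50, hill, converged, degenerate,
                      dose_range, sse, data) {
  structure(
    list(e0 = e0, einf = einf, ec50 = ec50, hill = hill,
         converged = converged, degenerate = degenerate,
         ic50 = NA_real_, ic50_censored = "none", auc = NA_real_,
         dose_range = dose_range, sse = sse, data = data),
    class = "drfit"
  )
}

# Model-free metrics when the optimizer fails everywhere.
fallback_fit <- function(pts, cmin, cmax, best) {
  agg <- stats::aggregate(viability ~ dose, data = pts[pts$dose > 0, ], FUN = mean)
  agg <- agg[order(agg$dose), ]
  x <- log10(agg$dose)
  y <- agg$viability

  if (all(y > 0.5)) {
    ic50 <- cmax; cens <- ">cmax"
  } else if (y[1] < 0.5) {
    ic50 <- cmin; cens <- "<cmin"
  } else {
    i <- which(y[-1] <= 0.5 & y[-length(y)] >= 0.5)[1]
    ic50 <- 10^(x[i] + (0.5 - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i]))
    cens <- "none"
  }
  yc <- clip(y, 0, 1)
  auc <- sum(diff(x) * (head(yc, -1) + tail(yc, -1)) / 2) / (x[length(x)] - x[1])
  fit <- new_drfit(
    e0 = y[1], einf = y[length(y)], ec50 = NA_real_, hill = NA_real_,
    converged = FALSE, degenerate = FALSE, dose_range = c(cmin, cmax),
    sse = if (is.null(best)) NA_real_ else best$sse, data = pts
  )
  fit$auc <- auc
  fit$ic50 <- ic50
  fit$ic50_censored <- cens
  fit
}

#' Absolute IC50 of a fitted curve
#'
#' The smallest dose within the tested range at which the fitted curve
#' crosses 50% viability, by closed-form inversion of the [fourpl()] model
#' (the absolute IC50 of a viability reduction to half of control — distinct
#' from the EC50 inflection parameter). Censored at the tested range:
#' `">cmax"` when fitted viability stays above 0.5 everywhere, `"<cmin"`
#' when the curve is already below 0.5 at the lowest tested dose. Censored
#' values carry the range bound as their numeric value so downstream fold
#' changes stay defined (conservative substitution).
#'
#' @param fit A `drfit` object from [fit_4pl()].
#' @return List with `value` (nM) and `censored` (`"none"`, `">cmax"`,
#'   `"<cmin"`).
#' @export
absolute_ic50 <- function(fit) {
  cmin <- fit$dose_range[1]
  cmax <- fit$dose_range[2]
  if (is.na(fit$hill)) {  # degenerate flat fit
    lvl <- fit$e0
    if (lvl > 0.5) return(list(value = cmax, censored = ">cmax"))
    if (lvl < 0.5) return(list(value = cmin, censored = "<cmin"))
    return(list(value = cmin, censored = "none"))
  }
  v_lo <- fourpl(cmin, fit$e0, fit$einf, fit$ec50, fit$hill)
  v_hi <- fourpl(cmax, fit$e0, fit$einf, fit$ec50, fit$hill)
  if (v_lo < 0.5) return(list(value = cmin, censored = "<cmin"))
  if (v_lo > 0.5 && v_hi > 0.5) return(list(value = cmax, censored = ">cmax"))
  if (v_lo == 0.5) return(list(value = cmin, censored = "none"))
  # Decreasing crossing: invert einf + (e0 - einf)/(1 + (c/ec50)^h) = 1/2.
  ratio <- (fit$e0 - 0.5) / (0.5 - fit$einf)
  c50 <- fit$ec50 * ratio^(1 / fit$hill)
  list(value = clip(c50, cmin, cmax), censored = "none")
}

#' Normalized area under a fitted dose-response curve
#'
#' Mean of the fitted viability (clipped to `[0, 1]`) over the tested
#' log10-dose window, by the trapezoid rule on an evenly spaced grid. This
#' is the GDSC-style sensitivity AUC: 1 for a fully resistant flat curve,
#' approaching 0 as the curve approaches complete kill everywhere; lower =
#' more sensitive.
#'
#' @param fit A `drfit` object.
#' @param n Number of quadrature nodes (default 1025; at least 257).
#' @return AUC fraction in `[0, 1]`.
#' @export
curve_auc <- function(fit, n = 1025) {
  cmin <- fit$dose_range[1]
  cmax <- fit$dose_range[2]
  if (cmin >= cmax) abort("curve_auc: dose range must satisfy cmin < cmax")
  if (is.na(fit$hill)) return(clip(fit$e0, 0, 1))
  x <- seq(log10(cmin), log10(cmax), length.out = max(n, 257))
  y <- clip(fourpl(10^x, fit$e0, fit$einf, fit$ec50, fit$hill), 0, 1)
  h <- x[2] - x[1]
  sum((head(y, -1) + tail(y, -1)) / 2 * h) / (x[length(x)] - x[1])
}

#' Fit dose-response curves for every cell line x compound series
#'
#' Grouped wrapper around [fit_4pl()]: takes a viability-point table (as
#' returned by [normalize_viability()]) and fits one curve per group,
#' returning a tidy fits table. Combination tables (with `anchor_compound`
#' and `anchor_dose` columns) are grouped per anchor as well, so the library
#' dose axis is fitted with the anchor held fixed.
#'
#' @param points Viability-point tibble with `cell_line`, `compound`,
#'   `dose`, `viability` (optionally `anchor_compound`, `anchor_dose`).
#' @param keep_fit Keep the underlying `drfit` objects in a `fit`
#'   list-column?
#' @param quadrature_n Passed to [fit_4pl()].
#' @return Tibble with one row per series: grouping columns plus `e0`,
#'   `einf`, `ec50_nM`, `hill`, `ic50_nM`, `ic50_censored`, `auc`,
#'   `converged`, `sse`.
#' @export
fit_dose_response <- function(points, keep_fit = FALSE, quadrature_n = 1025) {
  grp <- intersect(c("cell_line", "compound", "anchor_compound", "anchor_dose"),
                   names(points))
  points |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(df, key) {
      fit <- fit_4pl(df, quadrature_n = quadrature_n)
      row <- glance(fit)
      if (keep_fit) row$fit <- list(fit)
      row
    }) |>
    dplyr::ungroup()
}

#' @export
tidy.drfit <- function(x, ...) {
  tibble::tibble(
    term = c("e0", "einf", "ec50", "hill"),
    estimate = c(x$e0, x$einf, x$ec50, x$hill)
  )
}

#' @export
glance.drfit <- function(x, ...) {
  tibble::tibble(
    e0 = x$e0, einf = x$einf, ec50_nM = x$ec50, hill = x$hill,
    ic50_nM = x$ic50, ic50_censored = x$ic50_censored, auc = x$auc,
    converged = x$converged, sse = x$sse
  )
}

#' @export
print.drfit <- function(x, ...) {
  cat(sprintf(
    "<drfit> e0=%.3f einf=%.3f ec50=%.3g nM hill=%.3g | IC50 %s%.3g nM, AUC %.3f%s\n",
    x$e0, x$einf, x$ec50, x$hill,
    if (x$ic50_censored == "none") "" else paste0("(", x$ic50_censored, ") "),
    x$ic50, x$auc, if (x$converged) "" else " [not converged]"
  ))
  invisible(x)
}

#' @export
autoplot.drfit <- function(object, ...) {
  rng <- object$dose_range
  curve <- tibble::tibble(dose = 10^seq(log10(rng[1]), log10(rng[2]),
                                        length.out = 200))
  curve$viability <- fourpl(curve$dose, object$e0, object$einf,
                            object$ec50, object$hill)
  pts <- object$data[object$data$dose > 0, ]
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$dose, y = .data$viability)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (nM)", y = "viability (fraction of control)")
}

#' Column-wise AUC Z-scores across a cell-line panel
#'
#' Standardizes each compound's AUC values across all cell lines:
#' `z = (auc - mean) / sd` with the sample standard deviation (n - 1).
#' Missing entries stay missing; a constant column yields all zeros with a
#' warning. Negative Z-scores mark lines more sensitive than the panel
#' average for that compound.
#'
#' @param dataset A [sensitivity_dataset()].
#' @param compounds Optional character vector selecting compounds (default:
#'   all).
#' @return Matrix of Z-scores, cell lines x compounds.
#' @export
auc_zscore_matrix <- function(dataset, compounds = NULL) {
  auc <- dataset$auc
  if (!is.null(compounds)) {
    missing <- setdiff(compounds, colnames(auc))
    if (length(missing) > 0) {
      abort(paste0("compounds absent from dataset: ",
                   paste(missing, collapse = ", ")))
    }
    auc <- auc[, compounds, drop = FALSE]
  }
  n_obs <- colSums(!is.na(auc))
  if (any(n_obs < 3)) {
    abort(paste0("auc_zscore_matrix requires >= 3 non-missing AUC values; ",
                 "offending compound(s): ",
                 paste(colnames(auc)[n_obs < 3], collapse = ", ")))
  }
  mu <- colMeans(auc, na.rm = TRUE)
  sdv <- apply(auc, 2, sd, na.rm = TRUE)
  zero_sd <- sdv == 0
  if (any(zero_sd)) {
    warn(paste0("constant AUC column(s) set to zero Z-scores: ",
                paste(colnames(auc)[zero_sd], collapse = ", ")))
    sdv[zero_sd] <- 1
  }
  z <- sweep(sweep(auc, 2, mu, "-"), 2, sdv, "/")
  z[, zero_sd] <- ifelse(is.na(auc[, zero_sd]), NA_real_, 0)
  z
}

#' Classify cell lines as sensitive or insensitive at the top dose
#'
#' A line is insensitive to a compound when its measured viability remains
#' strictly above 50% at the top screened dose (10 uM by convention);
#' exactly 50% counts as sensitive. The classification is only defined at
#' the stated top dose, so callers must assert `top_dose_ok`.
#'
#' @param viability_at_top Viability fraction(s) at the top dose.
#' @param top_dose_ok Logical: was the measurement taken at the configured
#'   top dose? Anything else is an error, not a silent reclassification.
#' @return Character vector, `"sensitive"` or `"insensitive"`.
#' @export
classify_sensitivity <- function(viability_at_top, top_dose_ok = TRUE) {
  if (!all(top_dose_ok)) {
    abort("classify_sensitivity is undefined off the configured top dose")
  }
  ifelse(viability_at_top > 0.5, "insensitive", "sensitive")
}
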