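test_that("noise-free curves on the 6-dose grid are recovered to high accuracy", {
  f <- fit_4pl(make_points(grid6, oracle_4pl(grid6, 1, 0, 10, 1)))
  expect_lt(abs(f$ec50 - 10) / 10, 1e-6)
  expect_true(f$converged)

  set.seed(11)
  for (i in 1:25) {
    ec50 <- 10^runif(1, log10(0.1), log10(10000))
    hill <- runif(1, 0.8, 2.5)
    einf <- runif(1, 0, 0.3)
    f <- fit_4pl(make_points(grid6, oracle_4pl(grid6, 1, einf, ec50, hill)))
    expect_lt(abs(f$ec50 - ec50) / ec50, 1e-4)
    expect_lt(abs(f$einf - einf), 1e-4)
  }
})

test_that("absolute IC50 follows the analytic inversion, not the EC50", {
  # 0.4 + 0.6 / (1 + c/10) = 0.5  =>  c = 50
  f <- fit_4pl(make_points(grid6, oracle_4pl(grid6, 1, 0.4, 10, 1)))
  expect_equal(f$ic50, 50, tolerance = 1e-6)
  expect_equal(f$ic50_censored, "none")
  # V(ec50) = 0.5 whenever e0 = 1, einf = 0, for any hill
  for (h in c(0.7, 1, 2)) {
    f <- fit_4pl(make_points(grid6, oracle_4pl(grid6, 1, 0, 10, h)))
    expect_equal(f$ic50, 10, tolerance = 1e-5)
  }
})

test_that("absolute IC50 agrees with a bisection oracle on random curves", {
  set.seed(7)
  n_checked <- 0
  for (i in 1:200) {
    par <- list(e0 = runif(1, 0.9, 1.1), einf = runif(1, 0, 0.45),
                ec50 = 10^runif(1, -1, 4), hill = runif(1, 0.5, 4))
    fit <- structure(c(par, list(dose_range = c(0.1, 10000))), class = "drfit")
    ic <- absolute_ic50(fit)
    if (ic$censored != "none") next
    oracle <- bisect_ic50(par$e0, par$einf, par$ec50, par$hill, 0.1, 10000)
    expect_lt(abs(ic$value - oracle) / oracle, 1e-6)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 100)
})

test_that("IC50 censoring covers unreachable and pre-crossed curves", {
  fit_hi <- structure(list(e0 = 1, einf = 0.6, ec50 = 10, hill = 1,
                           dose_range = c(0.1, 10000)), class = "drfit")
  expect_equal(absolute_ic50(fit_hi)$censored, ">cmax")

  fit_lo <- structure(list(e0 = 1, einf = 0, ec50 = 0.001, hill = 2,
                           dose_range = c(0.1, 10000)), class = "drfit")
  expect_equal(absolute_ic50(fit_lo)$censored, "<cmin")
})

test_that("flat full-viability data censors IC50 and yields AUC 1", {
  f <- fit_4pl(make_points(grid6, rep(1, 6)))
  expect_false(f$converged)
  expect_equal(f$ic50_censored, ">cmax")
  expect_equal(f$auc, 1.0)
})

test_that("curve AUC matches fine quadrature and behaves at limits", {
  flat1 <- structure(list(e0 = 1, einf = 1, ec50 = 10, hill = 1,
                          dose_range = c(0.1, 10000)), class = "drfit")
  expect_equal(curve_auc(flat1), 1.0)
  flat0 <- structure(list(e0 = 0, einf = 0, ec50 = 10, hill = 1,
                          dose_range = c(0.1, 10000)), class = "drfit")
  expect_equal(curve_auc(flat0), 0.0)

  # steep curve centred at the geometric mid of the range: AUC -> 0.5
  mid <- sqrt(0.1 * 10000)
  steep <- structure(list(e0 = 1, einf = 0, ec50 = mid, hill = 8,
                          dose_range = c(0.1, 10000)), class = "drfit")
  expect_equal(curve_auc(steep),
               quadrature_auc(1, 0, mid, 8, 0.1, 10000), tolerance = 1e-6)
  expect_equal(curve_auc(steep), 0.5, tolerance = 0.02)

  set.seed(13)
  for (i in 1:20) {
    par <- list(e0 = runif(1, 0.8, 1.2), einf = runif(1, -0.1, 0.5),
                ec50 = 10^runif(1, -1, 4), hill = runif(1, 0.3, 5))
    fit <- structure(c(par, list(dose_range = c(0.1, 10000))), class = "drfit")
    expect_equal(curve_auc(fit),
                 quadrature_auc(par$e0, par$einf, par$ec50, par$hill,
                                0.1, 10000),
                 tolerance = 1e-5)
  }
})

test_that("pointwise-lower curves never have larger AUC", {
  set.seed(17)
  for (i in 1:20) {
    par <- list(e0 = runif(1, 0.9, 1.2), einf = runif(1, 0.1, 0.6),
                ec50 = 10^runif(1, 0, 3), hill = runif(1, 0.5, 3))
    drop <- runif(1, 0, 0.3)
    hi <- structure(c(par, list(dose_range = c(0.1, 10000))), class = "drfit")
    lo <- structure(list(e0 = par$e0 - drop, einf = par$einf - drop,
                         ec50 = par$ec50, hill = par$hill,
                         dose_range = c(0.1, 10000)), class = "drfit")
    expect_lte(curve_auc(lo), curve_auc(hi))
  }
})

test_that("fits are deterministic and reject insufficient data", {
  set.seed(19)
  pts <- make_points(grid6, oracle_4pl(grid6, 1, 0.2, 30, 1.5) + rnorm(6, 0, 0.05))
  f1 <- fit_4pl(pts)
  f2 <- fit_4pl(pts)
  expect_identical(glance(f1), glance(f2))

  expect_error(fit_4pl(make_points(c(1, 10, 100), c(1, 0.6, 0.2))),
               "insufficient")
})

test_that("model-free fallback interpolates IC50 and integrates observed points", {
  pts <- make_points(grid6, c(1, 0.95, 0.8, 0.6, 0.3, 0.1))
  fb <- synscreen:::fallback_fit(pts, 0.1, 10000, NULL)
  expect_false(fb$converged)
  # crossing between 100 nM (0.6) and 1000 nM (0.3): log-linear interpolation
  expect_equal(log10(fb$ic50), 2 + (0.5 - 0.6) / (0.3 - 0.6), tolerance = 1e-10)
  y <- c(1, 0.95, 0.8, 0.6, 0.3, 0.1)
  x <- log10(grid6)
  expect_equal(fb$auc, sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2) / 5)
})

test_that("AUC Z-scores standardize each compound across the panel", {
  auc <- cbind(A = c(0.2, 0.5, 0.8), B = c(0.5, 0.5, 0.5), C = c(0.1, 0.2, NA))
  rownames(auc) <- paste0("L", 1:3)
  ds <- sensitivity_dataset(
    auc,
    cell_meta = tibble::tibble(cell_line = paste0("L", 1:3),
                               pediatric = c(TRUE, FALSE, FALSE),
                               tumor_type = "t"),
    compound_meta = tibble::tibble(compound = c("A", "B", "C"),
                                   target = "x", target_pathway = "p")
  )
  expect_error(auc_zscore_matrix(ds), "3 non-missing")
  expect_warning(z <- auc_zscore_matrix(ds, compounds = c("A", "B")),
                 "constant")
  expect_equal(unname(z[, "A"]), c(-1, 0, 1))
  expect_equal(unname(z[, "B"]), c(0, 0, 0))
  expect_lt(abs(mean(z[, "A"])), 1e-12)
})

test_that("sensitivity classification is strict at the 50% boundary", {
  expect_equal(classify_sensitivity(c(0.62, 0.50, 0.10)),
               c("insensitive", "sensitive", "sensitive"))
  expect_error(classify_sensitivity(0.4, top_dose_ok = FALSE), "top dose")
})

test_that("grouped fitting returns one tidy row per series", {
  set.seed(23)
  sim <- gen_monotherapy_screen(n_lines = 2, compounds = 3,
                                noise = noise_model(0, 2), seed = 5)
  fits <- fit_dose_response(normalize_viability(sim$wells))
  expect_equal(nrow(fits), 6)
  expect_true(all(fits$converged))
  merged <- dplyr::inner_join(fits, sim$truth, by = c("cell_line", "compound"))
  expect_lt(max(abs(merged$ec50_nM - merged$ec50) / merged$ec50), 1e-4)
})
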