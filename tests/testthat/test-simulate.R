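test_that("generated wells close the loop through parsing and normalization", {
  sim <- gen_monotherapy_screen(n_lines = 2, compounds = 3, seed = 61)
  f <- tempfile(fileext = ".csv")
  write_screen_table(sim$wells, f)
  parsed <- read_screen_table(f)
  expect_equal(nrow(parsed), nrow(sim$wells))
  expect_silent(pts <- normalize_viability(parsed))
  expect_equal(nrow(pts), 2 * 3 * 6)
})

test_that("generators are deterministic in their seed and leave the RNG alone", {
  a <- gen_monotherapy_screen(n_lines = 1, compounds = 2, seed = 63)
  b <- gen_monotherapy_screen(n_lines = 1, compounds = 2, seed = 63)
  expect_identical(a, b)
  expect_false(identical(
    a, gen_monotherapy_screen(n_lines = 1, compounds = 2, seed = 64)
  ))

  s1 <- gen_anchored_library_screen(n_compounds = 5, seed = 65)
  s2 <- gen_anchored_library_screen(n_compounds = 5, seed = 65)
  expect_identical(s1, s2)

  d1 <- gen_sensitivity_dataset(n_ped = 5, n_adult = 10, n_compounds = 8,
                                n_pathways = 2, seed = 66)
  d2 <- gen_sensitivity_dataset(n_ped = 5, n_adult = 10, n_compounds = 8,
                                n_pathways = 2, seed = 66)
  expect_identical(d1$dataset$auc, d2$dataset$auc)

  set.seed(1234)
  before <- rnorm(1)
  set.seed(1234)
  invisible(gen_monotherapy_screen(n_lines = 1, compounds = 1, seed = 67))
  expect_identical(rnorm(1), before)
})

test_that("noise-free screens reproduce their truth through the full path", {
  sim <- gen_monotherapy_screen(n_lines = 1, compounds = 4,
                                noise = noise_model(0, 2), seed = 68)
  fits <- fit_dose_response(normalize_viability(sim$wells))
  merged <- dplyr::inner_join(fits, sim$truth, by = c("cell_line", "compound"))
  expect_lt(max(abs(merged$ec50_nM - merged$ec50) / merged$ec50), 1e-4)
  expect_lt(max(abs(merged$einf.x - merged$einf.y)), 1e-4)
})

test_that("default grids match the screen designs", {
  sim <- gen_monotherapy_screen(n_lines = 1, compounds = 1, seed = 69)
  expect_equal(sort(unique(sim$wells$dose[sim$wells$role == "sample"])),
               c(0.1, 1, 10, 100, 1000, 10000))
  g <- synscreen:::default_combo_grid()
  expect_equal(length(g), 10)
  expect_equal(g[1], 0.03)
  expect_equal(unique(round(g[-1] / g[-10], 9)), 5)
})

test_that("empirical viability noise matches the configured sigma", {
  sim <- gen_monotherapy_screen(n_lines = 2, compounds = 20,
                                noise = noise_model(0.05, 5), seed = 70)
  wells <- sim$wells[sim$wells$role == "sample", ]
  truth <- sim$truth
  par <- truth[match(paste(wells$cell_line, wells$compound),
                     paste(truth$cell_line, truth$compound)), ]
  v_true <- fourpl(wells$dose, par$e0, par$einf, par$ec50, par$hill)
  resid <- wells$signal / 10000 - v_true
  keep <- wells$signal > 0  # avoid the floor-truncated wells
  expect_gt(sum(keep), 1000)
  expect_lt(abs(sd(resid[keep]) - 0.05) / 0.05, 0.1)
})

test_that("independence grids carry zero excess without noise", {
  tr <- list(e0 = 1, einf = 0.1, ec50 = 30, hill = 1.2)
  g <- gen_combination_matrix(tr, tr, delta = 0, noise = noise_model(0, 1),
                              seed = 71)
  ex <- bliss_excess_matrix(g$matrix)
  expect_equal(max(abs(ex)), 0)
  expect_equal(average_bliss(ex), 0)
})

test_that("planted excess is recovered up to the clipping-aware expectation", {
  tr_a <- list(e0 = 1, einf = 0.3, ec50 = 100, hill = 1)
  tr_b <- list(e0 = 1, einf = 0.4, ec50 = 300, hill = 1.2)
  delta <- 0.2
  sigma <- 0.05
  g0 <- gen_combination_matrix(tr_a, tr_b, delta = delta,
                               noise = noise_model(0, 1), seed = 72)
  b_true <- g0$truth$expected_inhibition
  # closed-form expectation of the clipped observed inhibition minus the
  # clipped-margin Bliss expectation
  exp_obs <- clipped_normal_mean(b_true + delta, sigma)
  # margin expectation: E[clip(1 - (v + e), 0, 1)] = clipped_normal_mean(1 - v, sigma)
  fa_exp <- clipped_normal_mean(1 - fourpl(g0$matrix$dose_a, tr_a$e0, tr_a$einf,
                                           tr_a$ec50, tr_a$hill), sigma)
  fb_exp <- clipped_normal_mean(1 - fourpl(g0$matrix$dose_b, tr_b$e0, tr_b$einf,
                                           tr_b$ec50, tr_b$hill), sigma)
  expected_mean_excess <- mean(exp_obs - outer(fa_exp, fb_exp, bliss_expected))

  got <- vapply(1:25, function(i) {
    g <- gen_combination_matrix(tr_a, tr_b, delta = delta,
                                noise = noise_model(sigma, 1), seed = 720 + i)
    average_bliss(bliss_excess_matrix(g$matrix))
  }, numeric(1))
  expect_lt(abs(mean(got) - expected_mean_excess), 0.01)
  expect_lt(abs(mean(got) - delta), 0.05)
})

test_that("anchored screens have the stated geometry and planted flags", {
  scr <- gen_anchored_library_screen(n_compounds = 12,
                                     frac_synergistic = 0.25, seed = 73)
  expect_equal(nrow(scr$combo), 12 * 3 * 6)
  expect_equal(nrow(scr$mono), 12 * 6)
  expect_equal(sum(scr$truth$synergistic), 3)
  expect_equal(nrow(scr$anchor_mono), 3)
  # anchor doses invert the anchor truth at viabilities 0.85 / 0.75 / 0.50
  at <- scr$anchor_truth
  v <- fourpl(sort(unique(scr$combo$anchor_dose)), at$e0, at$einf, at$ec50,
              at$hill)
  expect_equal(sort(v, decreasing = TRUE), c(0.85, 0.75, 0.50),
               tolerance = 1e-9)
})

test_that("panel AUC values are truncated to [0, 1] and shifts are group-specific", {
  g <- gen_sensitivity_dataset(n_ped = 15, n_adult = 30, n_compounds = 20,
                               n_pathways = 4,
                               shifted_pathways = c(PATHWAY_01 = -0.3),
                               noise_sd = 0.3, seed = 74)
  auc <- g$dataset$auc
  expect_true(all(auc >= 0 & auc <= 1))
  ped <- g$dataset$cell_meta$pediatric
  in_path <- g$dataset$compound_meta$target_pathway == "PATHWAY_01"
  gap <- colMeans(auc[ped, , drop = FALSE]) - colMeans(auc[!ped, , drop = FALSE])
  expect_lt(mean(gap[in_path]), mean(gap[!in_path]) - 0.1)
})

test_that("expression generator plants the stated linear association", {
  panel <- gen_sensitivity_dataset(n_ped = 30, n_adult = 0, n_compounds = 3,
                                   n_pathways = 1, seed = 75)
  genes <- sprintf("G%04d", 1:100)
  ex <- gen_expression_dataset(100, list(S = genes[1:10]), beta = 2,
                               panel$dataset, "CPD002",
                               noise_sd = 1e-6, seed = 76)
  expect_equal(dim(ex$expression), c(100, 30))
  auc <- panel$dataset$auc[, "CPD002"]
  expect_equal(unname(ex$expression["G0001", ]), unname(-2 * auc),
               tolerance = 1e-4)
  expect_error(
    gen_expression_dataset(100, list(A = genes[1:5], B = genes[3:8]),
                           beta = 1, panel$dataset, "CPD001", seed = 77),
    "disjoint"
  )
})
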