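make_grid <- function(viab, dose_a, dose_b, mono_a, mono_b) {
  combination_matrix(viab, dose_a, dose_b, mono_a, mono_b,
                     cell_line = "L", compound_a = "A", compound_b = "B")
}

test_that("Bliss expectation is the independence formula", {
  expect_equal(bliss_expected(0, 0.4), 0.4)
  expect_equal(bliss_expected(0.5, 0.5), 0.75)
  expect_equal(bliss_expected(1, c(0, 0.3, 1)), c(1, 1, 1))
  expect_equal(bliss_expected(0.2, 0.3), bliss_expected(0.3, 0.2))
  expect_error(bliss_expected(1.2, 0.5), "\\[0, 1\\]")
})

test_that("exact independence gives an all-zero excess matrix", {
  da <- c(1, 10, 100)
  db <- c(5, 50, 500)
  fa <- c(0.1, 0.3, 0.7)
  fb <- c(0.2, 0.5, 0.9)
  viab <- 1 - outer(fa, fb, function(a, b) a + b - a * b)
  m <- make_grid(viab, da, db, 1 - fa, 1 - fb)
  ex <- bliss_excess_matrix(m)
  expect_equal(max(abs(ex)), 0)
  expect_equal(average_bliss(ex), 0)
})

test_that("excess is observed minus expected inhibition", {
  m <- make_grid(matrix(1 - 0.64), 1, 1, 1 - 0.2, 1 - 0.3)
  expect_equal(bliss_excess_matrix(m)[1, 1], 0.64 - 0.44)
})

test_that("missing margins undefine their whole row or column", {
  # A missing monotherapy margin for one dose of one drug removes every
  # combination cell that depends on it: 9 cells of a 9x9 grid.
  viab <- matrix(0.5, 9, 9)
  mono_b <- rep(0.8, 9)
  mono_b[4] <- NA
  m <- make_grid(viab, 1:9, 1:9, rep(0.7, 9), mono_b)
  ex <- bliss_excess_matrix(m)
  expect_equal(sum(!is.na(ex)), 72)
  expect_equal(average_bliss(ex), mean(ex, na.rm = TRUE))
})

test_that("average Bliss is the plain mean over defined cells", {
  expect_equal(average_bliss(matrix(c(0.1, -0.1), 1)), 0)
  set.seed(3)
  ex <- matrix(rnorm(9, 0, 0.1), 3)
  s <- 0
  for (i in 1:3) for (j in 1:3) s <- s + ex[i, j]
  expect_equal(average_bliss(ex), s / 9)
  expect_true(is.na(average_bliss(matrix(NA_real_, 2, 2))))
})

test_that("Bliss excess is symmetric under swapping the drugs", {
  set.seed(5)
  viab <- matrix(runif(30, 0.1, 1), 5, 6)
  m <- make_grid(viab, 1:5, 1:6, runif(5, 0.3, 1), runif(6, 0.3, 1))
  mt <- combination_matrix(t(viab), m$dose_b, m$dose_a, m$mono_b, m$mono_a)
  expect_equal(bliss_excess_matrix(mt), t(bliss_excess_matrix(m)))
})

test_that("Emax fold change handles identity, gain and null-baseline cases", {
  mono <- make_points(grid6, c(1, 1, 0.95, 0.9, 0.7, 0.6))
  combo <- make_points(grid6, c(0.9, 0.85, 0.6, 0.4, 0.2, 0.1))
  expect_equal(delta_emax(mono, combo), 0.9 / 0.4)
  expect_equal(delta_emax(mono, mono), 1.0)

  flat <- make_points(grid6, rep(1, 6))
  half <- make_points(grid6, c(1, 1, 1, 1, 0.8, 0.5))
  expect_equal(delta_emax(flat, half), Inf)
  expect_true(delta_emax(flat, half) > 5)
  expect_equal(delta_emax(flat, flat), 1.0)
  expect_error(delta_emax(mono, make_points(grid6[-6], rep(0.5, 5))), "top")
})

test_that("IC50 fold change substitutes censoring bounds conservatively", {
  expect_equal(delta_ic50(10, 2), 5)
  expect_equal(delta_ic50(list(value = 10000, censored = ">cmax"),
                          list(value = 100, censored = "none")), 100)
  both <- delta_ic50(list(value = 10000, censored = ">cmax"),
                     list(value = 10000, censored = ">cmax"))
  expect_equal(as.numeric(both), 1)
  expect_true(attr(both, "both_censored"))
  expect_equal(delta_ic50(7, 7), 1)
})

test_that("anchor averaging is the mean over defined anchors, with Inf absorbed", {
  pa <- tibble::tibble(anchor = c("IC15", "IC25", "IC50"),
                       delta_emax = c(1, 2, 3),
                       delta_ic50 = c(2, 4, 9),
                       bliss_avg = c(0.02, -0.01, 0.02))
  avg <- anchored_metrics(pa)
  expect_equal(avg$delta_ic50, 5)
  expect_equal(avg$bliss_avg, 0.01)

  one <- anchored_metrics(pa[2, ])
  expect_equal(one$delta_emax, 2)

  pa$delta_ic50[2] <- Inf
  expect_equal(anchored_metrics(pa)$delta_ic50, Inf)
  pa$bliss_avg[2] <- NA
  expect_equal(anchored_metrics(pa)$bliss_avg, 0.02)
  expect_error(anchored_metrics(pa[0, ]), "anchor")
})

test_that("hit selection uses strict thresholds on any of the three metrics", {
  m <- tibble::tibble(
    delta_emax = c(1.2, 1.0, 5.0, 6.0, NA),
    delta_ic50 = c(5.1, 1.0, 5.0, 1.0, NA),
    bliss_avg = c(-0.02, 0.001, 0.0, -0.5, NA)
  )
  expect_equal(select_hits(m), c(TRUE, TRUE, FALSE, TRUE, FALSE))
})

test_that("maximum effective synergy equals a brute-force qualifying scan", {
  # constructed case: the only sub-50% cell does not carry the largest excess
  viab <- matrix(0.9, 4, 4)
  viab[2, 3] <- 0.4
  ex <- matrix(0.5, 4, 4)
  ex[2, 3] <- 0.15
  m <- make_grid(viab, 1:4, 1:4, rep(0.9, 4), rep(0.9, 4))
  expect_equal(max_effective_synergy(m, ex), 0.15)
  expect_true(is.na(max_effective_synergy(m, ex, viability_cutoff = 0.3)))
  expect_equal(max_effective_synergy(make_grid(viab * 0.4, 1:4, 1:4,
                                               rep(0.9, 4), rep(0.9, 4)), ex),
               max(ex))

  set.seed(9)
  for (i in 1:100) {
    viab <- matrix(runif(100, 0, 1.1), 10, 10)
    ex <- matrix(rnorm(100, 0, 0.2), 10, 10)
    ex[sample(100, 5)] <- NA
    m <- make_grid(viab, 1:10, 1:10, runif(10), runif(10))
    brute <- suppressWarnings(
      max(ex[!is.na(ex) & viab < 0.5], na.rm = TRUE)
    )
    got <- max_effective_synergy(m, ex)
    if (is.infinite(brute)) expect_true(is.na(got)) else expect_equal(got, brute)
  }
})

test_that("cross-entity overlap intersects hits and excludes unscreened compounds", {
  hits <- tibble::tibble(
    cell_line = rep(c("L1", "L2"), each = 3),
    compound = rep(c("A", "B", "C"), 2),
    is_hit = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  )
  expect_equal(cross_entity_overlap(hits), c("B", "C"))

  # compound D: hit in four lines, unscreened (NA) in the fifth -> excluded
  hits5 <- tidyr::expand_grid(cell_line = paste0("L", 1:5),
                              compound = c("D", "E"))
  hits5$is_hit <- TRUE
  hits5$is_hit[hits5$cell_line == "L2" & hits5$compound == "D"] <- NA
  expect_equal(cross_entity_overlap(hits5), "E")

  disjoint <- tibble::tibble(cell_line = c("L1", "L2"),
                             compound = c("A", "B"),
                             is_hit = c(TRUE, TRUE))
  expect_equal(cross_entity_overlap(disjoint), character(0))
  expect_error(cross_entity_overlap(hits[hits$cell_line == "L1", ]), "2 cell")
})

test_that("planted hits propagate through selection and overlap on a fixture", {
  # 20 compounds x 5 lines; compounds H1..H3 planted as hits everywhere,
  # H4 hit in 4 lines and unscreened in one, the rest null.
  set.seed(31)
  compounds <- c(paste0("H", 1:4), paste0("N", 1:16))
  fixture <- tidyr::expand_grid(cell_line = paste0("L", 1:5),
                                compound = compounds)
  fixture$delta_emax <- 1
  fixture$delta_ic50 <- 1
  fixture$bliss_avg <- -0.05
  planted <- grepl("^H", fixture$compound)
  fixture$bliss_avg[planted] <- 0.15
  fixture$is_hit <- select_hits(fixture)
  expect_true(all(fixture$is_hit[planted]))
  expect_false(any(fixture$is_hit[!planted]))
  fixture$is_hit[fixture$compound == "H4" & fixture$cell_line == "L3"] <- NA
  expect_equal(cross_entity_overlap(fixture), c("H1", "H2", "H3"))
})
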