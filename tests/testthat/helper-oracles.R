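# Independent oracles used across the suite. These deliberately share no
# code with the package implementations they check.

# Bisection inversion of a 4PL curve at viability 0.5, in log-dose space.
# Assumes a decreasing curve crossing 0.5 inside [lo, hi].
bisect_ic50 <- function(e0, einf, ec50, hill, lo, hi, iters = 100) {
  f <- function(cc) einf + (e0 - einf) / (1 + (cc / ec50)^hill) - 0.5
  for (i in seq_len(iters)) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# Fine-grid trapezoid AUC of a clipped 4PL curve over log10 dose.
quadrature_auc <- function(e0, einf, ec50, hill, cmin, cmax, n = 20001) {
  x <- seq(log10(cmin), log10(cmax), length.out = n)
  v <- einf + (e0 - einf) / (1 + (10^x / ec50)^hill)
  v <- pmin(pmax(v, 0), 1)
  sum((v[-1] + v[-n]) / 2 * diff(x)) / (x[n] - x[1])
}

# Explicit element-by-element running-sum enrichment score. Ties between
# the positive and negative extremum resolve to the positive one (the
# package's documented convention).
brute_force_es <- function(ranking, set, p = 1) {
  N <- length(ranking)
  hit <- names(ranking) %in% set
  m <- sum(hit)
  denom_hit <- sum(abs(ranking[hit])^p)
  run <- 0
  hi <- 0
  lo <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      run <- run + if (denom_hit == 0) 1 / m else abs(ranking[i])^p / denom_hit
    } else {
      run <- run - 1 / (N - m)
    }
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  unname(if (hi >= -lo - 1e-12) hi else lo)
}

# Exact two-sided rank-sum p-value by enumeration of all group assignments
# (small n only, no ties assumed).
enumerate_ranksum_p <- function(x, y) {
  n1 <- length(x)
  vals <- c(x, y)
  r <- rank(vals)
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(vals), n1)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(vals) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Expectation of mean(clip(x + e, 0, 1)) for e ~ N(0, sd): closed form via
# truncated-normal moments, used as the clipping-aware oracle for planted
# Bliss excess.
clipped_normal_mean <- function(mu, sd) {
  if (sd == 0) return(pmin(pmax(mu, 0), 1))
  a <- (0 - mu) / sd
  b <- (1 - mu) / sd
  mu * (pnorm(b) - pnorm(a)) + sd * (dnorm(a) - dnorm(b)) + (1 - pnorm(b))
}

# 4PL viability used to derive truths independently of the package.
oracle_4pl <- function(dose, e0, einf, ec50, hill) {
  ifelse(dose <= 0, e0, einf + (e0 - einf) / (1 + (dose / ec50)^hill))
}

make_points <- function(dose, viability) tibble::tibble(dose = dose, viability = viability)

grid6 <- c(0.1, 1, 10, 100, 1000, 10000)
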