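test_that("per-population allele frequencies are count-exact and sum to one", {
  calls <- diplotype_calls(data.frame(
    sample_id = paste0("s", 1:3),
    allele1 = c("A", "A", "B"),
    allele2 = c("A", "B", "B"), stringsAsFactors = FALSE),
    alleles = c("A", "B"))
  tab <- allele_frequencies_by_population(calls, rep("EUR", 3))
  expect_equal(tab$freq[tab$allele == "A"], 0.5)   # dosages 2,1,0
  expect_equal(sum(tab$freq), 1)

  sim <- simulate_locus(locus_config(n_individuals = 1000, seed = 2024))
  truth <- truth_as_calls(sim$truth)
  t2 <- allele_frequencies_by_population(truth, rep("EUR", nrow(truth)))
  expect_equal(sum(t2$freq), 1)
  target <- c(0.59, 0.24, 0.17)
  se <- sqrt(target * (1 - target) / 2000)
  expect_true(all(abs(t2$freq - target) <= 3 * se))
})

test_that("LD r-squared is sign-invariant and null-calibrated", {
  x <- c(0, 1, 2, 1, 0, 2, 1)
  expect_equal(ld_r2(x, x), 1)
  expect_equal(ld_r2(x, 2 - x), 1)
  expect_error(ld_r2(x, rep(1, 7)), "constant")
  expect_error(ld_r2(c(1, NA), c(NA, 1)), "observations")
  set.seed(31)
  high <- 0L
  for (i in 1:40) {
    a <- sample(0:2, 1000, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    b <- sample(0:2, 1000, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    if (ld_r2(a, b) >= 0.01) high <- high + 1L
  }
  expect_lte(high / 40, 0.05)
})

# Independently coded Weir-Cockerham oracle (per-population sums written
# directly from the 1984 component formulas).
wc_oracle <- function(dosages, pops) {
  lv <- unique(pops)
  r <- length(lv)
  n_i <- sapply(lv, function(p) sum(pops == p))
  p_i <- sapply(lv, function(p) sum(dosages[pops == p]) / (2 * sum(pops == p)))
  h_i <- sapply(lv, function(p) mean(dosages[pops == p] == 1))
  nbar <- sum(n_i) / r
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  pbar <- sum(n_i * p_i) / sum(n_i)
  ssq <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / sum(n_i)
  a <- (nbar / nc) * (ssq - (pbar * (1 - pbar) - ((r - 1) / r) * ssq -
                             hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * ssq -
                              ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

test_that("FST matches an independent Weir-Cockerham oracle to 1e-12", {
  dos <- c(0, 1, 1, 2, 0, 0, 2, 2, 1, 0, 1, 2, 2, 2, 1, 0)
  pops <- rep(c("P1", "P2"), each = 8)
  expect_equal(fst_two_level(dos, pops), wc_oracle(dos, pops),
               tolerance = 1e-12)
  # unequal sizes, three populations
  set.seed(8)
  dos3 <- c(rbinom(20, 2, 0.2), rbinom(35, 2, 0.5), rbinom(50, 2, 0.8))
  pops3 <- rep(c("A", "B", "C"), c(20, 35, 50))
  expect_equal(fst_two_level(dos3, pops3), wc_oracle(dos3, pops3),
               tolerance = 1e-12)
})

test_that("FST hits its boundary cases", {
  # no differentiation
  set.seed(9)
  dos <- rbinom(1000, 2, 0.4)
  pops <- rep(c("P1", "P2"), each = 500)
  expect_lt(abs(fst_two_level(dos, pops)), 0.01)
  # fixed difference
  dosf <- c(rep(0, 50), rep(2, 50))
  popsf <- rep(c("P1", "P2"), each = 50)
  expect_equal(fst_two_level(dosf, popsf), 1)
  # merged identical populations ~ 0
  expect_lt(abs(fst_two_level(c(dos, dos), c(pops, rep(c("P3", "P4"),
                                                       each = 500)))), 0.01)
  expect_error(fst_two_level(dos, rep("P1", 1000)), ">= 2 populations")
  # hudson estimator agrees in the fixed-difference case
  expect_equal(fst_two_level(dosf, popsf, estimator = "hudson"), 1,
               tolerance = 1e-6)
})

test_that("mean recombination rate is the length-weighted interval mean", {
  map <- recombination_map(data.frame(pos = c(0, 100, 200),
                                      rate_cM_Mb = c(1, 3, 0),
                                      cum_cM = c(0, 1e-4, 4e-4)))
  expect_equal(mean_recombination_rate(map, c(0, 200)), 2)   # equal lengths
  expect_equal(mean_recombination_rate(map, c(0, 100)), 1)
  expect_equal(mean_recombination_rate(map, c(50, 150)), 2)
  # uniform map: any interval returns the common rate
  uni <- recombination_map(data.frame(pos = c(0, 10, 50, 100),
                                      rate_cM_Mb = 2.5,
                                      cum_cM = c(0, 10, 50, 100) * 2.5 / 1e6))
  expect_equal(mean_recombination_rate(uni, c(3, 77)), 2.5)
  expect_error(mean_recombination_rate(map, c(50, 50)), "positive length")
  expect_error(mean_recombination_rate(map, c(150, 300)), "outside")
})

test_that("interpolating the cumulative map reproduces mean rates (oracle)", {
  map <- random_rate_map(n_intervals = 40, seed = 10)
  for (iv in list(c(2001, 9001), c(501, 1501), c(333, 18777))) {
    by_rates <- mean_recombination_rate(map, iv)
    cm <- stats::approx(map$pos, map$cum_cM, xout = iv)$y
    by_map <- (cm[2] - cm[1]) / (iv[2] - iv[1]) * 1e6
    expect_equal(by_rates, by_map, tolerance = 1e-9)
  }
})

test_that("empirical p-values use the (k+1)/(n+1) convention and never hit 0", {
  pn <- permutation_null(0.5, c(0.6, 0.7, 0.8), tail = "lower")
  expect_equal(pn$empirical_p, 1 / 4)
  pn2 <- permutation_null(0.9, c(0.6, 0.7, 0.8), tail = "lower")
  expect_equal(pn2$empirical_p, 1)
  pn3 <- permutation_null(0.9, c(0.6, 0.7, 0.8), tail = "upper")
  expect_equal(pn3$empirical_p, 1 / 4)
})

test_that("recombination permutation test is reproducible and enumeration-exact", {
  map <- random_rate_map(n_intervals = 20, spacing_bp = 10, seed = 3)
  iv <- c(41, 81)
  a <- recomb_rate_permutation_test(map, iv, n_resamples = 99, seed = 17)
  b <- recomb_rate_permutation_test(map, iv, n_resamples = 99, seed = 17)
  expect_identical(a$null_values, b$null_values)
  expect_identical(a$empirical_p, b$empirical_p)

  # exhaustive agrees with a brute-force enumeration over all integer starts
  ex <- recomb_rate_permutation_test(map, iv, exhaustive = TRUE)
  len <- iv[2] - iv[1]
  starts <- seq(map$pos[1], map$pos[nrow(map)] - len)
  brute <- sapply(starts, function(s) mean_recombination_rate(map, c(s, s + len)))
  obs <- mean_recombination_rate(map, iv)
  expect_equal(ex$empirical_p, (sum(brute <= obs) + 1) / (length(brute) + 1))
})

test_that("observed global-minimum stretch earns the smallest attainable p", {
  # a map with a deep low-rate valley exactly at the query
  rates <- c(rep(5, 10), rep(0.01, 4), rep(5, 10))
  pos <- seq(0, by = 100, length.out = length(rates))
  map <- recombination_map(data.frame(pos = pos, rate_cM_Mb = rates,
                                      cum_cM = c(0, cumsum(rates[-length(rates)] *
                                                           diff(pos) / 1e6))))
  iv <- c(1000, 1400)
  res <- recomb_rate_permutation_test(map, iv, n_resamples = 999, seed = 5)
  # only starts inside the valley tie the observed minimum
  expect_lt(res$empirical_p, 0.05)
  expect_equal(res$tail, "lower")
})

test_that("recombination permutation p is null-calibrated on random maps", {
  map <- random_rate_map(n_intervals = 150, spacing_bp = 100, seed = 77)
  set.seed(78)
  len <- 1200
  lo <- map$pos[1]; hi <- map$pos[nrow(map)]
  ps <- vapply(1:400, function(i) {
    s <- sample(seq(lo, hi - len), 1)
    recomb_rate_permutation_test(map, c(s, s + len), n_resamples = 99,
                                 seed = 1000 + i)$empirical_p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("clinal test: perfect cline gives R2 = 1 and matching is enforced", {
  d <- seq(0, 9000, length.out = 10)
  target <- 0.1 + 0.00005 * d
  pool <- as.data.frame(matrix(runif(200 * 10), nrow = 200))
  names(pool) <- paste0("p", 1:10)
  pool$origin_freq <- runif(200, 0.05, 0.95)
  res <- clinal_permutation_test(target, d, pool, target_origin_freq = 0.5,
                                 match_tolerance = 0.2, n_resamples = 50,
                                 seed = 2)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_lt(res$empirical_p, 0.05)
  expect_error(
    clinal_permutation_test(target, d, pool, target_origin_freq = 5,
                            match_tolerance = 0),
    "no pool SNPs")
  expect_warning(
    clinal_permutation_test(target, d, pool, target_origin_freq = 0.5,
                            match_tolerance = 0.2, n_resamples = 5000,
                            seed = 2),
    "with replacement")
})

test_that("clinal observed R2 equals the lm R-squared", {
  d <- seq(0, 9000, length.out = 12)
  set.seed(12)
  f <- plogis(qlogis(0.3) + 0.0002 * d + rnorm(12, 0, 0.3))
  pool <- as.data.frame(matrix(runif(50 * 12), nrow = 50))
  pool$origin_freq <- 0.3
  res <- clinal_permutation_test(f, d, pool, target_origin_freq = 0.3,
                                 match_tolerance = 0.05, n_resamples = 20,
                                 seed = 3)
  expect_equal(res$r_squared, summary(stats::lm(f ~ d))$r.squared,
               tolerance = 1e-12)
})

test_that("clinal test p-values are null-calibrated", {
  d <- seq(0, 9000, length.out = 10)
  ps <- vapply(1:150, function(i) {
    pool_freqs <- simulate_clinal_frequencies(rep(d, 40), base_freq = 0.4,
                                              drift_sd = 0.5,
                                              seed = 5000 + i)$allele_freq
    pool <- as.data.frame(matrix(pool_freqs, nrow = 40, byrow = TRUE))
    pool$origin_freq <- 0.4
    target <- simulate_clinal_frequencies(d, base_freq = 0.4, drift_sd = 0.5,
                                          seed = 9000 + i)$allele_freq
    clinal_permutation_test(target, d, pool, target_origin_freq = 0.4,
                            match_tolerance = 1, n_resamples = 39,
                            seed = i, exhaustive = TRUE)$empirical_p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("waypoint distances follow the haversine closed form", {
  expect_equal(waypoint_distance(c(10, 20), c(10, 20)), 0)
  # 1 degree of longitude along the equator
  one_deg <- waypoint_distance(c(0, 0), c(0, 1))
  expect_equal(one_deg, 2 * pi * 6371 / 360, tolerance = 1e-6)
  # waypoint on the direct path leaves the distance unchanged
  direct <- waypoint_distance(c(0, 0), c(0, 10))
  via <- waypoint_distance(c(0, 0), c(0, 10), waypoints = rbind(c(0, 5)))
  expect_equal(via, direct, tolerance = 1e-6)
  # a detour is never shorter
  detour <- waypoint_distance(c(0, 0), c(0, 10), waypoints = rbind(c(20, 5)))
  expect_gt(detour, direct)
  expect_error(waypoint_distance(c(100, 0), c(0, 0)), "invalid")
})
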