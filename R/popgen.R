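#' Per-population allele frequencies of diplotype calls
#'
#' @param calls a [diplotype_calls] object.
#' @param pop_labels character vector of population codes, one per call row.
#' @return data.frame `pop_code`, `allele`, `freq`, `n` (called samples);
#'   per-allele frequencies sum to 1 within each population. Populations with
#'   no called samples are excluded with a warning.
#' @export
allele_frequencies_by_population <- function(calls, pop_labels) {
  if (length(pop_labels) != nrow(calls))
    stop("pop_labels must have one entry per sample")
  ok <- !is.na(calls$allele1)
  rows <- list()
  for (pop in unique(pop_labels)) {
    sel <- ok & pop_labels == pop
    if (!any(sel)) {
      warning("population ", pop, " has no called samples; excluded")
      next
    }
    n <- sum(sel)
    for (a in allele_set(calls)) {
      f <- (sum(calls$allele1[sel] == a) + sum(calls$allele2[sel] == a)) /
        (2 * n)
      rows[[length(rows) + 1L]] <-
        data.frame(pop_code = pop, allele = a, freq = f, n = n,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Linkage disequilibrium r-squared between two dosage vectors
#'
#' @param dosage_x,dosage_y numeric dosage vectors (0/1/2); pairs with missing
#'   values are dropped.
#' @return squared Pearson correlation.
#' @export
ld_r2 <- function(dosage_x, dosage_y) {
  ok <- !is.na(dosage_x) & !is.na(dosage_y)
  if (sum(ok) < 2L) stop("need >= 2 paired non-missing observations")
  x <- dosage_x[ok]; y <- dosage_y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("r-squared undefined for a constant dosage vector")
  stats::cor(x, y)^2
}

#' Weir-Cockerham fixation index for a biallelic locus
#'
#' Two-level (population / individual) Weir-Cockerham (1984) estimator
#' computed from genotype dosages; `estimator = "hudson"` gives the Hudson
#' estimator (two populations only) as an alternative.
#'
#' @param dosages numeric vector of genotype dosages 0/1/2 (`NA` dropped).
#' @param pop_labels population code per sample.
#' @param estimator `"wc"` (default) or `"hudson"`.
#' @return FST estimate (a single number).
#' @export
fst_two_level <- function(dosages, pop_labels, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  ok <- !is.na(dosages)
  dosages <- dosages[ok]; pop_labels <- pop_labels[ok]
  pops <- unique(pop_labels)
  ni <- vapply(pops, function(p) sum(pop_labels == p), numeric(1))
  if (length(pops) < 2L) stop("need >= 2 populations")
  if (any(ni < 2L)) stop("every population needs >= 2 samples")
  pi_ <- vapply(pops, function(p) mean(dosages[pop_labels == p]) / 2, numeric(1))
  hi <- vapply(pops, function(p) mean(dosages[pop_labels == p] == 1), numeric(1))

  if (estimator == "hudson") {
    if (length(pops) != 2L) stop("hudson estimator requires exactly 2 populations")
    num <- (pi_[1] - pi_[2])^2 -
      pi_[1] * (1 - pi_[1]) / (2 * ni[1] - 1) -
      pi_[2] * (1 - pi_[2]) / (2 * ni[2] - 1)
    den <- pi_[1] * (1 - pi_[2]) + pi_[2] * (1 - pi_[1])
    return(unname(num / den))
  }

  r <- length(pops)
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * pi_) / (r * nbar)
  s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  a / (a + b + c_)
}

#' Length-weighted mean recombination rate over an interval
#'
#' The map defines piecewise-constant rates on `[pos_i, pos_{i+1})`; the mean
#' over `[start, end]` weights each map interval's rate by its overlap length.
#'
#' @param map a `recombination_map`.
#' @param interval_bp numeric `c(start, end)`, within the map span, start <
#'   end.
#' @return mean rate in cM/Mb.
#' @export
mean_recombination_rate <- function(map, interval_bp) {
  stopifnot(inherits(map, "recombination_map"), length(interval_bp) == 2L)
  a <- interval_bp[1]; b <- interval_bp[2]
  if (b <= a) stop("interval must have positive length")
  if (a < map$pos[1] || b > map$pos[nrow(map)])
    stop("interval outside the map span [", map$pos[1], ", ",
         map$pos[nrow(map)], "]")
  starts <- map$pos[-nrow(map)]
  ends <- map$pos[-1]
  rates <- map$rate_cM_Mb[-nrow(map)]
  ov <- pmax(0, pmin(ends, b) - pmax(starts, a))
  sum(rates * ov) / (b - a)
}

#' Construct a permutation-null result
#'
#' @param observed observed statistic.
#' @param null_values resampled null statistics.
#' @param tail `"lower"` or `"upper"`.
#' @return list of class `permutation_null` with the empirical p-value
#'   `(k + 1) / (n + 1)` where `k` counts null values in the tail of the
#'   observed (ties included); p is never 0.
#' @export
permutation_null <- function(observed, null_values, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  k <- if (tail == "lower") sum(null_values <= observed)
       else sum(null_values >= observed)
  structure(list(observed = observed, null_values = null_values,
                 n_resamples = length(null_values),
                 empirical_p = (k + 1) / (length(null_values) + 1),
                 tail = tail),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation test (%s tail): observed = %s, n = %d, p = %s\n",
              x$tail, format(x$observed, digits = 4), x$n_resamples,
              format(x$empirical_p, digits = 4)))
  invisible(x)
}

#' Permutation test for reduced recombination rate
#'
#' Compares the mean recombination rate of the observed interval against the
#' rates of randomly placed same-length segments (integer bp starts drawn
#' uniformly over valid positions of the map span, with replacement); lower
#' tail by default. Segments overlapping the observed interval are not
#' excluded unless `exclude_observed = TRUE`.
#'
#' @param map a `recombination_map`.
#' @param interval_bp observed interval `c(start, end)`.
#' @param n_resamples number of random segments (the published analysis used
#'   10,000).
#' @param seed RNG seed.
#' @param exhaustive if `TRUE`, enumerate every possible integer start instead
#'   of sampling (`n_resamples` ignored).
#' @param exclude_observed drop resampled segments overlapping the observed
#'   interval.
#' @param tail tail direction (default `"lower"`: a rate reduction).
#' @return a `permutation_null`.
#' @export
recomb_rate_permutation_test <- function(map, interval_bp, n_resamples = 1000,
                                         seed = NULL, exhaustive = FALSE,
                                         exclude_observed = FALSE,
                                         tail = "lower") {
  stopifnot(inherits(map, "recombination_map"))
  len <- interval_bp[2] - interval_bp[1]
  lo <- map$pos[1]; hi <- map$pos[nrow(map)]
  if (hi - lo <= len) stop("map span must exceed the interval length")
  observed <- mean_recombination_rate(map, interval_bp)
  starts_all <- seq(lo, hi - len)
  if (exclude_observed) {
    ov <- starts_all < interval_bp[2] & (starts_all + len) > interval_bp[1]
    starts_all <- starts_all[!ov]
    if (!length(starts_all)) stop("no non-overlapping segments available")
  }
  starts <- if (exhaustive) starts_all else {
    if (n_resamples < 1) stop("n_resamples must be >= 1")
    with_seed(seed, sample(starts_all, n_resamples, replace = TRUE))
  }
  null_values <- vapply(starts, function(s)
    mean_recombination_rate(map, c(s, s + len)), numeric(1))
  permutation_null(observed, null_values, tail = tail)
}

#' Clinal-distribution permutation test with frequency-matched null SNPs
#'
#' The observed statistic is the R-squared of the OLS regression of a block
#' allele's per-population frequency on distance from the origin. The null is
#' the same R-squared computed for pool SNPs whose origin-region mean
#' frequency lies within `match_tolerance` of the target's; upper-tail
#' empirical p with the `(k+1)/(n+1)` convention.
#'
#' @param target_freqs per-population frequencies of the target allele.
#' @param distances_km per-population distances from the origin.
#' @param null_snp_pool data.frame: column `origin_freq` plus one frequency
#'   column per population, in the order of `distances_km` (any `snp_id`
#'   column is ignored for computation).
#' @param target_origin_freq origin-region mean frequency of the target.
#' @param match_tolerance absolute frequency-matching tolerance (default
#'   0.02).
#' @param n_resamples null draws (default 1000); if the matched pool is
#'   smaller, sampling is with replacement and a warning is issued.
#' @param seed RNG seed.
#' @param exhaustive if `TRUE`, use every matched pool SNP once.
#' @return a `permutation_null` with extra element `r_squared` (= observed).
#' @export
clinal_permutation_test <- function(target_freqs, distances_km, null_snp_pool,
                                    target_origin_freq,
                                    match_tolerance = 0.02,
                                    n_resamples = 1000, seed = NULL,
                                    exhaustive = FALSE) {
  stopifnot(length(target_freqs) == length(distances_km))
  if (stats::sd(distances_km) == 0) stop("distances are constant; R^2 undefined")
  # for simple OLS with intercept, R^2 equals the squared Pearson correlation
  r2_of <- function(freqs) {
    if (stats::sd(freqs) == 0) return(0)
    stats::cor(freqs, distances_km)^2
  }
  observed <- r2_of(target_freqs)
  pool <- as.data.frame(null_snp_pool)
  if (!"origin_freq" %in% names(pool))
    stop("null_snp_pool needs an 'origin_freq' column")
  freq_cols <- setdiff(names(pool), c("origin_freq", "snp_id"))
  if (length(freq_cols) != length(distances_km))
    stop("pool has ", length(freq_cols), " population columns but ",
         length(distances_km), " distances")
  matched <- which(abs(pool$origin_freq - target_origin_freq) <= match_tolerance)
  if (!length(matched))
    stop("no pool SNPs within match_tolerance = ", match_tolerance,
         " of origin frequency ", target_origin_freq)
  idx <- if (exhaustive) matched else {
    if (length(matched) < n_resamples) {
      warning("matched pool (", length(matched), ") smaller than n_resamples (",
              n_resamples, "); sampling with replacement")
      with_seed(seed, sample(matched, n_resamples, replace = TRUE))
    } else with_seed(seed, sample(matched, n_resamples, replace = FALSE))
  }
  fmat <- as.matrix(pool[idx, freq_cols, drop = FALSE])
  null_values <- apply(fmat, 1L, r2_of)
  res <- permutation_null(observed, null_values, tail = "upper")
  res$r_squared <- observed
  res
}

#' Great-circle distance along a waypoint route
#'
#' Sums haversine legs origin -> waypoints -> destination on a sphere of
#' radius 6371 km, emulating migration-path distances routed around major
#' water masses.
#'
#' @param origin_lat_lon numeric `c(lat, lon)` in degrees.
#' @param pop_lat_lon destination `c(lat, lon)` in degrees.
#' @param waypoints optional matrix / data.frame of intermediate `lat, lon`
#'   rows (in travel order).
#' @return distance in km.
#' @export
waypoint_distance <- function(origin_lat_lon, pop_lat_lon, waypoints = NULL) {
  check_ll <- function(p) {
    if (length(p) != 2L || abs(p[1]) > 90 || abs(p[2]) > 180)
      stop("invalid latitude/longitude: ", paste(p, collapse = ", "))
  }
  check_ll(origin_lat_lon); check_ll(pop_lat_lon)
  pts <- rbind(origin_lat_lon)
  if (!is.null(waypoints)) {
    waypoints <- as.matrix(waypoints)
    apply(waypoints, 1L, check_ll)
    pts <- rbind(pts, waypoints)
  }
  pts <- rbind(pts, pop_lat_lon)
  total <- 0
  for (i in seq_len(nrow(pts) - 1L)) {
    # geosphere expects (lon, lat); radius 6371 km
    total <- total + geosphere::distHaversine(
      pts[i, c(2, 1)], pts[i + 1L, c(2, 1)], r = 6371000) / 1000
  }
  total
}
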