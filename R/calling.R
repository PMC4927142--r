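#' Construct a diplotype-calls object
#'
#' Per-sample unordered pairs of named block alleles, with the k-means cluster
#' each call came from and a distance-to-centroid quality score.
#'
#' @param calls data.frame with columns `sample_id`, `allele1`, `allele2`
#'   (pair stored sorted), `cluster`, `quality`.
#' @param alleles character vector: the declared allele set.
#' @return data.frame of class `diplotype_calls` with attribute `alleles`.
#' @export
diplotype_calls <- function(calls, alleles) {
  calls <- as.data.frame(calls)
  stopifnot(all(c("sample_id", "allele1", "allele2") %in% names(calls)))
  ok <- is.na(calls$allele1) | (calls$allele1 %in% alleles &
                                calls$allele2 %in% alleles)
  if (!all(ok))
    stop("calls contain alleles outside the declared set: ",
         paste(setdiff(unique(c(calls$allele1, calls$allele2)), alleles),
               collapse = ", "))
  swap <- !is.na(calls$allele1) & calls$allele1 > calls$allele2
  tmp <- calls$allele1[swap]
  calls$allele1[swap] <- calls$allele2[swap]
  calls$allele2[swap] <- tmp
  if (!"cluster" %in% names(calls)) calls$cluster <- NA_integer_
  if (!"quality" %in% names(calls)) calls$quality <- NA_real_
  attr(calls, "alleles") <- alleles
  class(calls) <- c("diplotype_calls", "data.frame")
  calls
}

#' Allele set of a diplotype-calls object
#' @param calls a [diplotype_calls] object.
#' @return character vector of allele names.
#' @export
allele_set <- function(calls) attr(calls, "alleles")

#' Classical MDS embedding of genotype dosages
#'
#' Computes classical (Torgerson) metric MDS of the Euclidean distances
#' between per-sample genotype-dosage vectors (0/1/2 per SNP; sites missing in
#' either sample are dropped pairwise, with the usual rescaling). Equivalent
#' to PCA of the centered dosage matrix when there is no missingness. The sign
#' of each component is fixed so that the reference sample (if given) has a
#' non-negative first coordinate; absent a reference, the sample with the
#' largest absolute loading on each component is made positive.
#'
#' @param gm a [genotype_matrix].
#' @param region optional region (string or `c(start, end)`) passed to
#'   [subset_region].
#' @param n_components number of components (default 2).
#' @param reference_sample optional sample id anchoring the sign of the first
#'   component.
#' @return numeric matrix samples x components with rownames, attribute `eig`
#'   carrying the eigenvalues.
#' @export
mds_embed <- function(gm, region = NULL, n_components = 2,
                      reference_sample = NULL) {
  if (!is.null(region)) gm <- subset_region(gm, region)
  if (n_variants(gm) < 2L) stop("region contains fewer than 2 SNPs")
  if (n_samples(gm) < 3L) stop("need at least 3 samples")
  dos <- dosage_matrix(gm)
  d <- stats::dist(dos)    # Euclidean; NAs dropped pairwise with rescaling
  if (anyNA(d)) stop("distance undefined for some sample pair (all-missing overlap)")
  fit <- stats::cmdscale(d, k = n_components, eig = TRUE)
  coords <- fit$points
  # components whose eigenvalue is numerically zero carry no geometry;
  # zero them so identical samples embed identically
  eig_pos <- pmax(fit$eig, 0)
  negligible <- eig_pos[seq_len(ncol(coords))] <= 1e-8 * max(eig_pos)
  coords[, negligible] <- 0
  for (j in seq_len(ncol(coords))) {
    flip <- if (!is.null(reference_sample) && j == 1L) {
      if (!reference_sample %in% rownames(coords))
        stop("reference sample not found: ", reference_sample)
      coords[reference_sample, 1L] < 0
    } else {
      coords[which.max(abs(coords[, j])), j] < 0
    }
    if (isTRUE(flip)) coords[, j] <- -coords[, j]
  }
  attr(coords, "eig") <- fit$eig
  coords
}

#' Cluster MDS coordinates into diplotype groups
#'
#' k-means with `k = a(a+1)/2` clusters for `a` declared alleles (all
#' homozygote and heterozygote combinations), 20 seeded restarts, best inertia
#' kept.
#'
#' @param coords embedding from [mds_embed].
#' @param n_alleles declared number of block alleles `a` (2 or 3 supported).
#' @param seed RNG seed.
#' @param n_restarts k-means restarts (default 20).
#' @return the `stats::kmeans` fit (with `cluster`, `centers`, `tot.withinss`).
#' @export
cluster_diplotypes <- function(coords, n_alleles, seed = NULL,
                               n_restarts = 20) {
  if (!n_alleles %in% c(2L, 3L))
    stop("n_alleles must be 2 or 3 (k > 6 clusters is not supported)")
  coords <- as.matrix(coords)
  k <- n_alleles * (n_alleles + 1L) / 2L
  if (nrow(unique(coords)) < k)
    stop("fewer than k = ", k, " distinct points; cannot form clusters")
  kmeans_dedup(coords, k, seed = seed, n_restarts = n_restarts)
}

# k-means run on the de-duplicated, canonically ordered point set (so results
# are invariant to sample order and robust to heavily duplicated coordinates),
# followed by nearest-centroid assignment of every sample; ties break to the
# lowest cluster index.
kmeans_dedup <- function(coords, k, seed = NULL, n_restarts = 20) {
  ord <- do.call(order, lapply(seq_len(ncol(coords)), function(j) coords[, j]))
  uq <- unique(coords[ord, , drop = FALSE])
  km <- with_seed(seed, stats::kmeans(uq, centers = k, nstart = n_restarts,
                                      iter.max = 500))
  d2 <- outer(rowSums(coords^2), rowSums(km$centers^2), `+`) -
    2 * coords %*% t(km$centers)
  cl <- max.col(-d2, ties.method = "first")
  names(cl) <- rownames(coords)
  structure(list(cluster = cl, centers = km$centers,
                 size = tabulate(cl, k),
                 tot.withinss = sum(d2[cbind(seq_along(cl), cl)])),
            class = "kmeans")
}

#' Label clusters as homozygote / heterozygote diplotypes
#'
#' With `k = a(a+1)/2` clusters, the `a` homozygote clusters are those whose
#' centroids maximize the sum of pairwise distances (the extreme clusters);
#' every remaining cluster is labeled the heterozygote of the homozygote pair
#' whose centroid midpoint is nearest. Alleles are named `H1, H2, ...`, with
#' `H1` the allele of the reference sample's homozygote cluster (reference
#' genomes map to the non-variant allele) or, absent a reference, of the
#' largest homozygote cluster; the rest are ordered by decreasing homozygote
#' cluster size.
#'
#' @param km k-means fit from [cluster_diplotypes].
#' @param coords the coordinates that were clustered (rownames = sample ids).
#' @param n_alleles declared allele count `a`.
#' @param reference_sample optional id of a sample carrying two copies of the
#'   reference allele.
#' @param ambiguity_tol relative tolerance below which a heterozygote centroid
#'   equidistant to two midpoints is flagged ambiguous (calls from that
#'   cluster are marked low-confidence via `quality = NA`).
#' @return list of class `cluster_model`:
#'   \describe{
#'     \item{calls}{a [diplotype_calls] object.}
#'     \item{centers}{centroid matrix.}
#'     \item{cluster_labels}{character vector mapping cluster -> diplotype.}
#'     \item{allele_freqs}{implied allele frequencies.}
#'     \item{hwe}{per-allele Hardy-Weinberg chi-square tests
#'       (see [hwe_test]).}
#'     \item{ambiguous_clusters}{integer vector of flagged clusters.}
#'   }
#' @export
label_clusters <- function(km, coords, n_alleles, reference_sample = NULL,
                           ambiguity_tol = 1e-6) {
  coords <- as.matrix(coords)
  a <- n_alleles
  k <- a * (a + 1L) / 2L
  centers <- km$centers
  if (nrow(centers) != k)
    stop("expected k = ", k, " clusters, got ", nrow(centers))

  cdist <- as.matrix(stats::dist(centers))
  combos <- utils::combn(k, a)
  spread <- apply(combos, 2L, function(s) sum(cdist[s, s]) / 2)
  hom_clusters <- combos[, which.max(spread)]

  het_clusters <- setdiff(seq_len(k), hom_clusters)
  pairs <- utils::combn(a, 2)   # indices into hom_clusters
  midpoints <- t(apply(pairs, 2L, function(p)
    colMeans(centers[hom_clusters[p], , drop = FALSE])))

  ambiguous <- integer(0)
  het_pair <- integer(length(het_clusters))
  if (length(het_clusters)) for (i in seq_along(het_clusters)) {
    dm <- sqrt(colSums((t(midpoints) - centers[het_clusters[i], ])^2))
    ord <- order(dm)
    het_pair[i] <- ord[1L]
    if (length(dm) > 1L &&
        (dm[ord[2L]] - dm[ord[1L]]) <= ambiguity_tol * max(dm[ord[2L]], 1e-12))
      ambiguous <- c(ambiguous, het_clusters[i])
  }

  # allele naming: H1 = reference sample's homozygote cluster (or largest)
  sizes <- km$size[hom_clusters]
  allele_order <- order(-sizes)
  if (!is.null(reference_sample)) {
    if (!reference_sample %in% rownames(coords))
      stop("reference sample not found: ", reference_sample)
    ref_cluster <- km$cluster[[reference_sample]]
    pos <- match(ref_cluster, hom_clusters)
    if (!is.na(pos)) {
      allele_order <- c(pos, setdiff(allele_order, pos))
    } else {
      warning("reference sample is not in a homozygote cluster; ",
              "falling back to largest-cluster naming")
    }
  }
  allele_names <- character(a)
  allele_names[allele_order] <- paste0("H", seq_len(a))

  cluster_labels <- character(k)
  cluster_labels[hom_clusters] <-
    paste(allele_names, allele_names, sep = "/")
  if (length(het_clusters)) for (i in seq_along(het_clusters)) {
    p <- pairs[, het_pair[i]]
    ab <- sort(allele_names[p])
    cluster_labels[het_clusters[i]] <- paste(ab[1L], ab[2L], sep = "/")
  }

  assigned <- km$cluster
  lab <- cluster_labels[assigned]
  parts <- do.call(rbind, strsplit(lab, "/", fixed = TRUE))
  quality <- sqrt(rowSums((coords - centers[assigned, , drop = FALSE])^2))
  quality[assigned %in% ambiguous] <- NA_real_
  calls <- diplotype_calls(
    data.frame(sample_id = rownames(coords),
               allele1 = parts[, 1L], allele2 = parts[, 2L],
               cluster = assigned, quality = quality,
               stringsAsFactors = FALSE),
    alleles = sort(allele_names))

  freqs <- implied_allele_freqs(calls)
  hwe <- hwe_test(calls)
  structure(list(calls = calls, centers = centers,
                 cluster_labels = cluster_labels,
                 allele_freqs = freqs, hwe = hwe,
                 ambiguous_clusters = ambiguous),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model:", nrow(x$centers), "clusters ->",
      paste(x$cluster_labels, collapse = " "), "\n")
  cat("allele frequencies:",
      paste(sprintf("%s=%.3f", names(x$allele_freqs), x$allele_freqs),
            collapse = " "), "\n")
  invisible(x)
}

#' Call diplotypes within a region by MDS + k-means
#'
#' Convenience wrapper: [mds_embed] then [cluster_diplotypes] then
#' [label_clusters].
#'
#' @inheritParams mds_embed
#' @inheritParams cluster_diplotypes
#' @inheritParams label_clusters
#' @return a `cluster_model` (see [label_clusters]).
#' @export
call_diplotypes <- function(gm, region = NULL, n_alleles = 3, seed = NULL,
                            reference_sample = NULL) {
  coords <- mds_embed(gm, region, n_components = 2,
                      reference_sample = reference_sample)
  km <- cluster_diplotypes(coords, n_alleles, seed = seed)
  label_clusters(km, coords, n_alleles, reference_sample = reference_sample)
}

#' Implied allele frequencies of diplotype calls
#'
#' `freq(allele) = (2 * n_hom + n_het) / (2 n)` over non-missing calls; the
#' frequencies sum to 1.
#'
#' @param calls a [diplotype_calls] object.
#' @return named numeric vector.
#' @export
implied_allele_freqs <- function(calls) {
  ok <- !is.na(calls$allele1)
  n2 <- 2L * sum(ok)
  vapply(allele_set(calls), function(a)
    (sum(calls$allele1[ok] == a) + sum(calls$allele2[ok] == a)) / n2,
    numeric(1))
}

#' Hardy-Weinberg chi-square test
#'
#' Each allele is folded to carrier dose 0/1/2 and the genotype counts are
#' tested against the `p^2, 2pq, q^2` expectations with a 1-df chi-square
#' (the screening form; an exact test is available with `exact = TRUE`).
#' Alleles with `p < flag_threshold` are flagged.
#'
#' @param x a [diplotype_calls] object, or a numeric vector `c(n0, n1, n2)` of
#'   genotype counts (non-carrier, heterozygote, homozygote).
#' @param exact if `TRUE`, use the exact conditional test (enumeration of
#'   heterozygote counts given allele counts) instead of the chi-square.
#' @param flag_threshold p-value below which the allele is flagged
#'   (default 0.01, the conventional screening cut).
#' @return for counts: list `chi_square`, `p_value`; for calls: data.frame
#'   with one row per allele (`allele`, `n0`, `n1`, `n2`, `chi_square`,
#'   `p_value`, `flagged`).
#' @export
hwe_test <- function(x, exact = FALSE, flag_threshold = 0.01) {
  if (is.numeric(x)) {
    stopifnot(length(x) == 3L)
    return(hwe_counts(x[1], x[2], x[3], exact))
  }
  stopifnot(inherits(x, "diplotype_calls"))
  calls <- x[!is.na(x$allele1), , drop = FALSE]
  if (nrow(calls) == 0L) stop("no called samples")
  rows <- lapply(allele_set(x), function(a) {
    dose <- (calls$allele1 == a) + (calls$allele2 == a)
    n0 <- sum(dose == 0); n1 <- sum(dose == 1); n2 <- sum(dose == 2)
    ht <- hwe_counts(n0, n1, n2, exact)
    data.frame(allele = a, n0 = n0, n1 = n1, n2 = n2,
               chi_square = ht$chi_square, p_value = ht$p_value,
               flagged = is.finite(ht$p_value) & ht$p_value < flag_threshold)
  })
  do.call(rbind, rows)
}

hwe_counts <- function(n0, n1, n2, exact = FALSE) {
  n <- n0 + n1 + n2
  if (n == 0L) stop("zero informative samples")
  p <- (2 * n2 + n1) / (2 * n)
  if (p == 0 || p == 1)
    return(list(chi_square = 0, p_value = 1))
  if (exact) return(list(chi_square = NA_real_, p_value = hwe_exact(n0, n1, n2)))
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi <- sum((c(n0, n1, n2) - e)^2 / e)
  list(chi_square = chi, p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

# Exact HWE test: sum of probabilities of heterozygote counts no more likely
# than the observed one, conditional on allele counts.
hwe_exact <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na_ <- n1 + 2 * n2          # minor-or-major allele count; symmetric
  hets <- seq(na_ %% 2, min(na_, 2 * n - na_), by = 2)
  logp <- vapply(hets, function(h) {
    hom2 <- (na_ - h) / 2
    hom0 <- n - h - hom2
    lgamma(n + 1) - lgamma(hom0 + 1) - lgamma(h + 1) - lgamma(hom2 + 1) +
      h * log(2) + lgamma(na_ + 1) + lgamma(2 * n - na_ + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n1, hets)]
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' One-dimensional sparse-panel fallback caller
#'
#' For sparse genotyping panels where only a handful of tag SNPs are
#' available, 2-D MDS no longer separates all six diplotype clusters. This
#' caller uses the first MDS component of the panel, verifies the expected
#' 5-cluster pattern by 1-D k-means (two diplotypes collapse onto the same
#' coordinate), calls the two tag-resolvable alleles directly from
#' orientation-aligned mean tag dosages, and infers the third allele's
#' homozygotes as the samples simultaneously carrying zero copies of both
#' resolvable alleles.
#'
#' @param gm a [genotype_matrix] containing the panel SNPs.
#' @param tag_panel data.frame with columns `snp_id`, `allele`, `r` (signed
#'   correlation between SNP dosage and allele dosage, from
#'   [discover_tag_snps]); exactly two distinct alleles must be present.
#' @param other_allele name given to the inferred third allele
#'   (default `"H_other"`).
#' @param seed RNG seed for the k-means check.
#' @return a [diplotype_calls] object (cluster = 1-D k-means cluster ordered
#'   along the component).
#' @export
call_1d_fallback <- function(gm, tag_panel, other_allele = "H_other",
                             seed = NULL) {
  stopifnot(all(c("snp_id", "allele", "r") %in% names(tag_panel)))
  if (nrow(tag_panel) == 0L) stop("empty tag panel")
  alleles <- unique(tag_panel$allele)
  if (length(alleles) != 2L)
    stop("tag panel must cover exactly 2 resolvable alleles, got ",
         length(alleles))
  keep <- gm$variants$id %in% tag_panel$snp_id
  if (!any(keep)) stop("no panel SNPs present in genotype matrix")
  gm_panel <- genotype_matrix(gm$sample_ids,
                              gm$variants[keep, , drop = FALSE],
                              gm$alleles[, keep, drop = FALSE], gm$pop_labels)

  coords <- mds_embed(gm_panel, n_components = 1)
  if (nrow(unique(coords)) < 5L)
    stop("fewer than 5 occupied clusters on the first MDS component; ",
         "use the 2-D caller instead")
  km <- kmeans_dedup(coords, 5, seed = seed)
  if (length(unique(km$cluster)) < 5L)
    stop("fewer than 5 occupied clusters on the first MDS component; ",
         "use the 2-D caller instead")
  cl_order <- order(km$centers[, 1L])
  cluster_rank <- match(km$cluster, cl_order)

  dos <- dosage_matrix(gm_panel)
  dose_of <- function(a) {
    tags <- tag_panel[tag_panel$allele == a, , drop = FALSE]
    cols <- match(tags$snp_id, gm_panel$variants$id)
    present <- !is.na(cols)
    if (!any(present)) stop("no tags present for allele ", a)
    aligned <- dos[, cols[present], drop = FALSE]
    neg <- tags$r[present] < 0
    aligned[, neg] <- 2 - aligned[, neg, drop = FALSE]
    rowMeans(aligned, na.rm = TRUE)
  }
  raw1 <- dose_of(alleles[1L])
  raw2 <- dose_of(alleles[2L])
  d1 <- pmin(pmax(round(raw1), 0), 2)
  d2 <- pmin(pmax(round(raw2), 0), 2)
  over <- d1 + d2 > 2
  if (any(over)) {
    # resolve rare conflicts by trimming the dose farther from its raw value
    trim1 <- abs(d1 - raw1) >= abs(d2 - raw2)
    d1[over & trim1] <- pmax(d1[over & trim1] - 1L, 0)
    d2[over & !trim1] <- pmax(d2[over & !trim1] - 1L, 0)
    still <- d1 + d2 > 2
    d2[still] <- 2 - d1[still]
  }
  pair <- function(a, b) {
    rest <- 2L - a - b
    al <- c(rep(alleles[1L], a), rep(alleles[2L], b),
            rep(other_allele, rest))
    sort(al)
  }
  calls <- t(mapply(pair, d1, d2))
  diplotype_calls(
    data.frame(sample_id = gm$sample_ids,
               allele1 = calls[, 1L], allele2 = calls[, 2L],
               cluster = cluster_rank,
               quality = abs(coords[, 1L] - km$centers[km$cluster, 1L]),
               stringsAsFactors = FALSE),
    alleles = sort(c(alleles, other_allele)))
}

#' Discover tag SNPs for each block allele
#'
#' Computes the squared Pearson correlation between each allele's dosage
#' (0/1/2 per sample) and every SNP's dosage; SNPs at or above the threshold
#' are reported with their r-squared and signed r. Monomorphic SNPs are
#' skipped. The conventional tagging threshold is `r^2 > 0.9`.
#'
#' @param calls a [diplotype_calls] object.
#' @param gm a [genotype_matrix] sharing `calls`' samples.
#' @param r2_threshold minimum r-squared (default 0.9).
#' @return data.frame `allele`, `snp_id`, `r2`, `r`, sorted by allele then
#'   decreasing r2.
#' @export
discover_tag_snps <- function(calls, gm, r2_threshold = 0.9) {
  idx <- match(calls$sample_id, gm$sample_ids)
  if (anyNA(idx)) stop("calls contain samples absent from genotype matrix")
  dos <- dosage_matrix(gm)[idx, , drop = FALSE]
  sds <- apply(dos, 2L, stats::sd, na.rm = TRUE)
  poly <- !is.na(sds) & sds > 0
  out <- lapply(allele_set(calls), function(a) {
    adose <- (calls$allele1 == a) + (calls$allele2 == a)
    if (stats::sd(adose, na.rm = TRUE) == 0) return(NULL)
    r <- suppressWarnings(
      stats::cor(dos[, poly, drop = FALSE], adose,
                 use = "pairwise.complete.obs"))[, 1L]
    r2 <- r^2
    sel <- !is.na(r2) & r2 >= r2_threshold
    if (!any(sel)) return(NULL)
    df <- data.frame(allele = a,
                     snp_id = gm$variants$id[poly][sel],
                     r2 = r2[sel], r = r[sel], stringsAsFactors = FALSE)
    df[order(-df$r2), ]
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(allele = character(0), snp_id = character(0),
                      r2 = numeric(0), r = numeric(0))
  rownames(out) <- NULL
  out
}

#' Agreement between two diplotype call sets up to allele relabeling
#'
#' Cluster-derived allele names are arbitrary, so accuracy against truth is
#' the best agreement over all bijections between the two allele sets.
#'
#' @param calls a [diplotype_calls] object.
#' @param truth a [diplotype_calls] object (e.g. from [truth_as_calls]) or a
#'   data.frame with `sample_id`, `allele1`, `allele2`.
#' @return list `accuracy` (fraction of samples whose unordered pair matches
#'   under the best mapping), `mapping` (named vector truth allele -> call
#'   allele), `n` (samples compared).
#' @export
diplotype_accuracy <- function(calls, truth) {
  idx <- match(calls$sample_id, truth$sample_id)
  if (anyNA(idx)) stop("samples in calls missing from truth")
  t1 <- as.character(truth$allele1[idx])
  t2 <- as.character(truth$allele2[idx])
  c1 <- as.character(calls$allele1)
  c2 <- as.character(calls$allele2)
  ok <- !is.na(c1) & !is.na(t1)
  truth_alleles <- sort(unique(c(t1[ok], t2[ok])))
  call_alleles <- allele_set(calls)
  if (is.null(call_alleles)) call_alleles <- sort(unique(c(c1[ok], c2[ok])))
  if (length(call_alleles) < length(truth_alleles))
    stop("call allele set smaller than truth allele set")
  perms <- perms_of(call_alleles, length(truth_alleles))
  best <- 0; best_map <- NULL
  for (i in seq_len(nrow(perms))) {
    map <- stats::setNames(perms[i, ], truth_alleles)
    m1 <- map[t1[ok]]; m2 <- map[t2[ok]]
    agree <- (m1 == c1[ok] & m2 == c2[ok]) | (m1 == c2[ok] & m2 == c1[ok])
    acc <- mean(agree)
    if (acc > best) { best <- acc; best_map <- map }
  }
  list(accuracy = best, mapping = best_map, n = sum(ok))
}

# all ordered selections of size k from x
perms_of <- function(x, k) {
  if (k == 1L) return(matrix(x, ncol = 1L))
  out <- NULL
  for (i in seq_along(x)) {
    sub <- perms_of(x[-i], k - 1L)
    out <- rbind(out, cbind(x[i], sub))
  }
  out
}
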