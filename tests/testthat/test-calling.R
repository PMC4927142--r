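test_that("identical samples embed to identical coordinates", {
  a <- rbind(c(0L, 1L, 0L), c(1L, 0L, 1L),
             c(0L, 1L, 0L), c(1L, 0L, 1L),
             c(0L, 0L, 0L), c(0L, 0L, 1L))
  gm <- genotype_matrix(c("s1", "s2", "s3"),
                        data.frame(chrom = "1", pos = 1:3 * 100L,
                                   id = paste0("v", 1:3), ref = "A", alt = "G"),
                        a)
  coords <- mds_embed(gm)
  expect_equal(coords["s1", ], coords["s2", ], tolerance = 1e-10)
})

test_that("MDS reproduces the double-centered Gram eigen-solution", {
  # independent oracle: eigendecomposition of -0.5 * J D2 J
  dos <- matrix(c(0, 1, 2,
                  2, 1, 0,
                  1, 1, 1,
                  0, 0, 2), nrow = 4, byrow = TRUE)
  a <- matrix(0L, 8, 3)
  for (i in 1:4) {
    a[2 * i - 1, ] <- as.integer(dos[i, ] >= 1)
    a[2 * i, ] <- as.integer(dos[i, ] == 2)
  }
  gm <- genotype_matrix(paste0("s", 1:4),
                        data.frame(chrom = "1", pos = 1:3 * 100L,
                                   id = paste0("v", 1:3), ref = "A", alt = "G"),
                        a)
  coords <- mds_embed(gm, n_components = 2)

  D2 <- as.matrix(dist(dos))^2
  n <- nrow(D2)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  eig <- eigen(B, symmetric = TRUE)
  oracle <- eig$vectors[, 1:2] %*% diag(sqrt(eig$values[1:2]))
  expect_equal(abs(matrix(coords, ncol = 2)), abs(oracle), tolerance = 1e-10)
})

test_that("three-clade locus separates into six clusters matching truth", {
  sim <- default_sim()
  model <- call_diplotypes(sim$genotypes, region = block_region(sim),
                           n_alleles = 3, seed = 11)
  expect_equal(nrow(model$centers), 6L)
  acc <- diplotype_accuracy(model$calls, truth_as_calls(sim$truth))
  expect_gte(acc$accuracy, 0.99)
  # silhouette-style separation: distance to own centroid far below
  # distance between centroids
  expect_lt(max(model$calls$quality, na.rm = TRUE),
            min(dist(model$centers)))
})

test_that("k-means cluster count follows the diplotype formula", {
  sim <- default_sim()
  coords <- mds_embed(sim$genotypes, region = block_region(sim))
  km2 <- cluster_diplotypes(coords, n_alleles = 2, seed = 1)
  expect_equal(nrow(km2$centers), 3L)
  km3 <- cluster_diplotypes(coords, n_alleles = 3, seed = 1)
  expect_equal(nrow(km3$centers), 6L)
  expect_error(cluster_diplotypes(coords[1:4, ], 3, seed = 1), "distinct")
})

test_that("cluster labeling follows homozygote / midpoint geometry", {
  # hand-built geometry: homozygote centroids at the triangle corners,
  # heterozygotes at the midpoints
  centers <- rbind(c(0, 0), c(4, 0), c(0, 4),
                   c(2, 0), c(0, 2), c(2, 2))
  pts <- centers[rep(1:6, each = 12), ] +
    matrix(stats::rnorm(144, 0, 0.05), ncol = 2)
  rownames(pts) <- paste0("s", seq_len(nrow(pts)))
  km <- cluster_diplotypes(pts, 3, seed = 2)
  model <- label_clusters(km, pts, 3)
  labs <- model$cluster_labels
  hom <- grepl("^(H1/H1|H2/H2|H3/H3)$", labs)
  expect_equal(sum(hom), 3L)
  # cluster at (2,0) must be the heterozygote of corners (0,0) and (4,0)
  mid_cluster <- which.min(colSums((t(model$centers) - c(2, 0))^2))
  corner_a <- which.min(colSums((t(model$centers) - c(0, 0))^2))
  corner_b <- which.min(colSums((t(model$centers) - c(4, 0))^2))
  hom_names <- vapply(strsplit(labs[c(corner_a, corner_b)], "/"),
                      `[`, character(1), 1)
  expect_setequal(strsplit(labs[mid_cluster], "/")[[1]], hom_names)
  # largest homozygote cluster gets allele H1 (no reference sample given)
  expect_true(any(labs == "H1/H1"))
})

test_that("reference sample anchors allele naming", {
  sim <- default_sim()
  truth <- truth_as_calls(sim$truth)
  # pick a clade-2 homozygote as "reference genome carrier"
  ref <- truth$sample_id[truth$allele1 == "C2" & truth$allele2 == "C2"][1]
  model <- call_diplotypes(sim$genotypes, region = block_region(sim),
                           n_alleles = 3, seed = 11, reference_sample = ref)
  ref_call <- model$calls[model$calls$sample_id == ref, ]
  expect_equal(ref_call$allele1, "H1")
  expect_equal(ref_call$allele2, "H1")
})

test_that("one-dimensional collinear geometry labels the middle as heterozygote", {
  pts <- matrix(c(rnorm(20, 0, 0.01), rnorm(20, 2, 0.01), rnorm(20, 4, 0.01)),
                ncol = 1)
  rownames(pts) <- paste0("s", 1:60)
  km <- cluster_diplotypes(pts, 2, seed = 3)
  model <- label_clusters(km, pts, 2)
  mid <- which.min(abs(model$centers - 2))
  expect_true(model$cluster_labels[mid] %in% c("H1/H2"))
})

test_that("calls are invariant to sample order", {
  sim <- simulate_locus(locus_config(n_individuals = 150, seed = 55))
  gm <- sim$genotypes
  perm <- sample(n_samples(gm))
  rows <- as.vector(rbind(2 * perm - 1, 2 * perm))
  gm_perm <- genotype_matrix(gm$sample_ids[perm], gm$variants,
                             gm$alleles[rows, , drop = FALSE])
  m1 <- call_diplotypes(gm, region = block_region(sim), n_alleles = 3, seed = 4)
  m2 <- call_diplotypes(gm_perm, region = block_region(sim), n_alleles = 3,
                        seed = 4)
  c1 <- m1$calls[order(m1$calls$sample_id), ]
  c2 <- m2$calls[order(m2$calls$sample_id), ]
  # allele naming is size/reference based, hence order-invariant
  expect_equal(c1$allele1, c2$allele1)
  expect_equal(c1$allele2, c2$allele2)
})

test_that("implied allele frequencies sum to one and follow the count formula", {
  sim <- default_sim()
  model <- call_diplotypes(sim$genotypes, region = block_region(sim),
                           n_alleles = 3, seed = 11)
  freqs <- implied_allele_freqs(model$calls)
  expect_equal(sum(freqs), 1)
  a <- "H1"
  hom <- sum(model$calls$allele1 == a & model$calls$allele2 == a)
  het <- sum(xor(model$calls$allele1 == a, model$calls$allele2 == a))
  expect_equal(unname(freqs[a]),
               (2 * hom + het) / (2 * nrow(model$calls)))
})

test_that("heterozygote centroids sit nearest their own homozygote midpoints", {
  sim <- default_sim()
  model <- call_diplotypes(sim$genotypes, region = block_region(sim),
                           n_alleles = 3, seed = 11)
  labs <- model$cluster_labels
  centers <- model$centers
  hom_of <- function(a) which(labs == paste(a, a, sep = "/"))
  for (cl in which(!labs %in% paste(c("H1", "H2", "H3"),
                                    c("H1", "H2", "H3"), sep = "/"))) {
    pair <- strsplit(labs[cl], "/")[[1]]
    own_mid <- colMeans(centers[c(hom_of(pair[1]), hom_of(pair[2])), ])
    other_pairs <- setdiff(c("H1/H2", "H1/H3", "H2/H3"), labs[cl])
    d_own <- sqrt(sum((centers[cl, ] - own_mid)^2))
    for (op in other_pairs) {
      ab <- strsplit(op, "/")[[1]]
      mid <- colMeans(centers[c(hom_of(ab[1]), hom_of(ab[2])), ])
      expect_lt(d_own, sqrt(sum((centers[cl, ] - mid)^2)))
    }
  }
})

test_that("Hardy-Weinberg chi-square matches hand-computed expectations", {
  exact_hwe <- hwe_test(c(25, 50, 25))
  expect_equal(exact_hwe$chi_square, 0)
  expect_equal(exact_hwe$p_value, 1)

  dev <- hwe_test(c(10, 0, 10))     # expectations 5 / 10 / 5
  expect_equal(dev$chi_square, 20)
  expect_equal(dev$p_value, stats::pchisq(20, 1, lower.tail = FALSE))
  expect_lt(abs(dev$p_value - 7.7e-6), 1e-7)

  # exact test agrees with chi-square direction on a clear deviation
  expect_lt(hwe_test(c(10, 0, 10), exact = TRUE)$p_value, 0.01)

  sim <- default_sim()
  model <- call_diplotypes(sim$genotypes, region = block_region(sim),
                           n_alleles = 3, seed = 11)
  hw <- model$hwe
  expect_equal(nrow(hw), 3L)
  # random-mating generator: alleles should not be flagged at the 0.01 screen
  expect_false(any(hw$flagged))
})

test_that("tag SNP discovery obeys r2 thresholds and monotonicity", {
  sim <- default_sim()
  truth <- truth_as_calls(sim$truth)
  tags95 <- discover_tag_snps(truth, sim$genotypes, r2_threshold = 0.95)
  tags99 <- discover_tag_snps(truth, sim$genotypes, r2_threshold = 0.99)
  expect_true(all(tags95$r2 >= 0.95))
  expect_lte(nrow(tags99), nrow(tags95))      # threshold monotonicity
  expect_true(all(tags99$snp_id %in% tags95$snp_id))
  # a SNP identical to an allele dosage must be reported with r2 = 1
  dose2 <- encode_dosage(truth, "C2", "additive")
  hap_dose <- sim$truth$chromosome_clade == 2
  gm2 <- sim$genotypes
  gm2$alleles <- cbind(gm2$alleles, as.integer(hap_dose))
  gm2$variants <- rbind(gm2$variants,
                        data.frame(chrom = "15",
                                   pos = max(gm2$variants$pos) + 1000L,
                                   id = "perfect", ref = "A", alt = "G"))
  tags <- discover_tag_snps(truth, gm2, r2_threshold = 0.9)
  perfect <- tags[tags$snp_id == "perfect", ]
  expect_equal(perfect$allele, "C2")
  expect_equal(perfect$r2, 1)
  # flank SNPs are independent of the clades: never tagged
  expect_false(any(grepl("^flk", tags$snp_id)))
})

test_that("1-D fallback calls from an 8-SNP tag panel recover the truth", {
  sim <- simulate_locus(locus_config(n_individuals = 600, seed = 321))
  truth <- truth_as_calls(sim$truth)
  tags <- discover_tag_snps(truth, sim$genotypes, r2_threshold = 0.9)
  # resolvable alleles: the two tagged clades; 4 tags each
  tagged <- unique(tags$allele)
  expect_gte(length(tagged), 2L)
  panel <- do.call(rbind, lapply(tagged[1:2], function(a)
    utils::head(tags[tags$allele == a, ], 4)))
  calls <- call_1d_fallback(sim$genotypes, panel, seed = 12)
  expect_equal(sort(unique(calls$cluster)), 1:5)
  acc <- diplotype_accuracy(calls, truth)
  expect_gte(acc$accuracy, 0.99)
  expect_error(call_1d_fallback(sim$genotypes, panel[0, ], seed = 1), "empty")
  expect_error(call_1d_fallback(sim$genotypes, panel[panel$allele ==
                                                     tagged[1], ]),
               "exactly 2")
})

test_that("double heterozygotes are bookkept as a pair of resolvable alleles", {
  sim <- simulate_locus(locus_config(n_individuals = 600, seed = 321))
  truth <- truth_as_calls(sim$truth)
  tags <- discover_tag_snps(truth, sim$genotypes, r2_threshold = 0.9)
  tagged <- unique(tags$allele)[1:2]
  panel <- do.call(rbind, lapply(tagged, function(a)
    utils::head(tags[tags$allele == a, ], 4)))
  calls <- call_1d_fallback(sim$genotypes, panel, seed = 12)
  both <- truth$allele1 == tagged[1] & truth$allele2 == tagged[2] |
    truth$allele1 == tagged[2] & truth$allele2 == tagged[1]
  called_pairs <- paste(calls$allele1, calls$allele2)[both]
  expect_true(all(called_pairs == paste(sort(tagged)[1], sort(tagged)[2])))
})
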