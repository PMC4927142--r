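#' Configuration for a simulated extended-haplotype locus
#'
#' Describes a locus with a central block of suppressed recombination carrying
#' deeply diverged haplotype clades, flanked on both sides by freely
#' recombining SNPs. Defaults emulate a three-clade block with European-like
#' clade frequencies 0.59 / 0.24 / 0.17.
#'
#' @param n_individuals number of diploid samples.
#' @param n_block_snps SNPs inside the block (default 200).
#' @param n_flank_snps SNPs on each side of the block (default 300).
#' @param clade_freqs probability vector of founder clade frequencies; must
#'   sum to 1 and have length >= 2 (default `c(0.59, 0.24, 0.17)`).
#' @param divergence fraction of block sites at which each clade pair is
#'   guaranteed to differ (a dedicated, disjoint site set per pair; one
#'   designated founder is flipped at each site, so additional incidental
#'   differences accrue to other pairs). Requires
#'   `choose(k,2) * ceiling(divergence * n_block_snps) <= n_block_snps`.
#' @param within_clade_mut per-site, per-chromosome flip probability inside
#'   the block (within-clade diversity).
#' @param flank_recomb per-meiosis crossover probability in the flanks, used
#'   by [simulate_trios].
#' @param snp_spacing_bp distance between adjacent SNPs in bp (default 1000).
#' @param chrom chromosome label (default `"15"`).
#' @param seed RNG seed.
#' @return a list of class `locus_config`.
#' @export
locus_config <- function(n_individuals = 500,
                         n_block_snps = 200,
                         n_flank_snps = 300,
                         clade_freqs = c(0.59, 0.24, 0.17),
                         divergence = 0.3,
                         within_clade_mut = 0.01,
                         flank_recomb = 0.01,
                         snp_spacing_bp = 1000,
                         chrom = "15",
                         seed = NULL) {
  if (length(clade_freqs) < 2L) stop("clade_freqs must have length >= 2")
  if (abs(sum(clade_freqs) - 1) > 1e-8) stop("clade_freqs must sum to 1")
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  if (within_clade_mut < 0 || within_clade_mut > 1)
    stop("within_clade_mut must be in [0, 1]")
  k <- length(clade_freqs)
  d <- ceiling(divergence * n_block_snps)
  if (choose(k, 2) * d > n_block_snps)
    stop("divergence too high: pairwise difference sets do not fit in the block")
  structure(list(n_individuals = n_individuals, n_block_snps = n_block_snps,
                 n_flank_snps = n_flank_snps, clade_freqs = clade_freqs,
                 divergence = divergence, within_clade_mut = within_clade_mut,
                 flank_recomb = flank_recomb, snp_spacing_bp = snp_spacing_bp,
                 chrom = chrom, seed = seed),
            class = "locus_config")
}

#' Simulate a genotype matrix with a planted haplotype block
#'
#' Block SNPs: each chromosome copies the haplotype of its founder clade with
#' independent per-site flips at rate `within_clade_mut`. Flank SNPs: allele
#' frequencies drawn once from Uniform(0.05, 0.95) and alleles sampled
#' independently per chromosome (free recombination). Founder clades are made
#' to differ by flipping one designated founder at each site of a disjoint
#' per-pair site set (clade 1 is never flipped and acts as the reference-like
#' background).
#'
#' @param config a [locus_config].
#' @return list with elements
#'   \describe{
#'     \item{genotypes}{a [genotype_matrix]; block SNP ids carry prefix `blk`,
#'       flank ids `flk`.}
#'     \item{truth}{list of class `truth_labels`: `chromosome_clade` (integer
#'       clade per haplotype row), `diplotype` (data.frame `sample_id`,
#'       `allele1`, `allele2`, sorted), `founders` (clade x block-site allele
#'       matrix), `block_cols` (column indices of block SNPs).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_locus <- function(config) {
  stopifnot(inherits(config, "locus_config"))
  with_seed(config$seed, {
    n <- config$n_individuals
    nb <- config$n_block_snps
    nf <- config$n_flank_snps
    k <- length(config$clade_freqs)
    n_chr <- 2L * n
    m <- nb + 2L * nf

    # founder clade haplotypes over the block
    base <- stats::rbinom(nb, 1L, 0.5)
    founders <- matrix(rep(base, each = k), nrow = k)
    d <- ceiling(config$divergence * nb)
    if (d > 0 && k >= 2) {
      pairs <- utils::combn(k, 2)
      sites <- sample.int(nb, d * ncol(pairs))
      for (p in seq_len(ncol(pairs))) {
        s <- sites[((p - 1L) * d + 1L):(p * d)]
        flip <- max(pairs[, p])   # flip the higher-indexed clade of the pair
        founders[flip, s] <- 1L - founders[flip, s]
      }
    }

    chrom_clade <- sample.int(k, n_chr, replace = TRUE,
                              prob = config$clade_freqs)
    block <- founders[chrom_clade, , drop = FALSE]
    if (config$within_clade_mut > 0) {
      flips <- matrix(stats::rbinom(n_chr * nb, 1L, config$within_clade_mut),
                      nrow = n_chr)
      block <- abs(block - flips)
    }

    flank_freq <- stats::runif(2L * nf, 0.05, 0.95)
    flanks <- matrix(stats::rbinom(n_chr * 2L * nf, 1L,
                                   rep(flank_freq, each = n_chr)),
                     nrow = n_chr)
    alleles <- cbind(flanks[, seq_len(nf), drop = FALSE],
                     block,
                     flanks[, nf + seq_len(nf), drop = FALSE])
    storage.mode(alleles) <- "integer"

    block_cols <- (nf + 1L):(nf + nb)
    ids <- character(m)
    ids[block_cols] <- paste0("blk", seq_len(nb))
    ids[-block_cols] <- paste0("flk", seq_len(2L * nf))
    variants <- data.frame(
      chrom = config$chrom,
      pos = seq_len(m) * config$snp_spacing_bp,
      id = ids, ref = "A", alt = "G", stringsAsFactors = FALSE)

    sample_ids <- sprintf("ind%04d", seq_len(n))
    gm <- genotype_matrix(sample_ids, variants, alleles)

    dip <- matrix(chrom_clade, ncol = 2L, byrow = TRUE)
    dip <- t(apply(dip, 1L, sort))
    truth <- structure(
      list(chromosome_clade = chrom_clade,
           diplotype = data.frame(sample_id = sample_ids,
                                  allele1 = dip[, 1L], allele2 = dip[, 2L],
                                  stringsAsFactors = FALSE),
           founders = founders,
           block_cols = block_cols),
      class = "truth_labels")
    list(genotypes = gm, truth = truth, config = config)
  })
}

#' Truth labels as diplotype calls
#'
#' Converts the generator's truth labels into a [diplotype_calls] object with
#' alleles named `C1`, `C2`, ... so that truth can flow through the same
#' downstream operations as real calls.
#'
#' @param truth `truth_labels` from [simulate_locus].
#' @return a [diplotype_calls] object.
#' @export
truth_as_calls <- function(truth) {
  stopifnot(inherits(truth, "truth_labels"))
  k <- nrow(truth$founders)
  diplotype_calls(
    data.frame(sample_id = truth$diplotype$sample_id,
               allele1 = paste0("C", truth$diplotype$allele1),
               allele2 = paste0("C", truth$diplotype$allele2),
               cluster = NA_integer_, quality = 0,
               stringsAsFactors = FALSE),
    alleles = paste0("C", seq_len(k)))
}

#' Simulate trio offspring from parental genotypes
#'
#' Parents `2i - 1` and `2i` of `parents` form couple `i`. Each child receives
#' one uniformly chosen haplotype from each parent; with probability
#' `flank_recomb` per meiosis a single crossover is placed uniformly among the
#' inter-SNP intervals outside `block_cols` (the block itself never
#' recombines). Each transmitted allele is then flipped independently with
#' probability `error_rate` (genotyping error).
#'
#' @param parents a [genotype_matrix] with at least `2 * n_trios` samples.
#' @param n_trios number of trios to generate.
#' @param error_rate per-allele flip probability in `[0, 1]`.
#' @param seed RNG seed.
#' @param truth optional `truth_labels` for the parents; if given, children's
#'   true diplotypes are derived from the transmitted chromosomes.
#' @param block_cols optional block column indices (taken from `truth` if
#'   present) restricting crossovers to the flanks.
#' @param flank_recomb per-meiosis crossover probability (default 0).
#' @return list with `genotypes` (parents followed by children), `pedigree`
#'   (a [pedigree_table]), and `child_truth` (data.frame or `NULL`).
#' @export
simulate_trios <- function(parents, n_trios, error_rate = 0, seed = NULL,
                           truth = NULL, block_cols = NULL, flank_recomb = 0) {
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (n_samples(parents) < 2L * n_trios)
    stop("need at least 2 * n_trios parent samples")
  if (is.null(block_cols) && !is.null(truth)) block_cols <- truth$block_cols
  with_seed(seed, {
    m <- n_variants(parents)
    flank_idx <- setdiff(seq_len(m - 1L), block_cols)   # crossover points
    child_alleles <- matrix(NA_integer_, nrow = 2L * n_trios, ncol = m)
    child_clade <- integer(2L * n_trios)

    transmit <- function(parent_i) {
      h <- sample.int(2L, 1L)
      rows <- c(2L * parent_i - 1L, 2L * parent_i)
      hap <- parents$alleles[rows[h], ]
      src <- h
      if (flank_recomb > 0 && length(flank_idx) &&
          stats::runif(1) < flank_recomb) {
        cut <- sample(flank_idx, 1L)
        other <- parents$alleles[rows[3L - h], ]
        hap <- c(hap[seq_len(cut)], other[(cut + 1L):m])
        # clade of the transmitted block follows whichever haplotype carries it
        if (!is.null(block_cols)) {
          src <- if (cut < min(block_cols)) 3L - h else h
        }
      }
      if (error_rate > 0) {
        flip <- stats::rbinom(m, 1L, error_rate) == 1L
        hap[flip] <- 1L - hap[flip]
      }
      list(hap = as.integer(hap), row = rows[src])
    }

    for (t in seq_len(n_trios)) {
      f <- transmit(2L * t - 1L)
      mo <- transmit(2L * t)
      child_alleles[2L * t - 1L, ] <- f$hap
      child_alleles[2L * t, ] <- mo$hap
      if (!is.null(truth)) {
        child_clade[2L * t - 1L] <- truth$chromosome_clade[f$row]
        child_clade[2L * t] <- truth$chromosome_clade[mo$row]
      }
    }

    child_ids <- sprintf("child%04d", seq_len(n_trios))
    ped <- pedigree_table(data.frame(
      child = child_ids,
      father = parents$sample_ids[2L * seq_len(n_trios) - 1L],
      mother = parents$sample_ids[2L * seq_len(n_trios)],
      stringsAsFactors = FALSE))
    gm <- genotype_matrix(c(parents$sample_ids, child_ids),
                          parents$variants,
                          rbind(parents$alleles, child_alleles),
                          NULL)
    child_truth <- NULL
    if (!is.null(truth)) {
      dip <- t(apply(matrix(child_clade, ncol = 2L, byrow = TRUE), 1L, sort))
      child_truth <- data.frame(sample_id = child_ids,
                                allele1 = dip[, 1L], allele2 = dip[, 2L],
                                stringsAsFactors = FALSE)
    }
    list(genotypes = gm, pedigree = ped, child_truth = child_truth)
  })
}

#' Specification of planted phenotype / expression effects
#'
#' @param recessive_effects named numeric vector: phenotype-unit shift applied
#'   to homozygotes of each named clade (names `C1`, `C2`, ... matching
#'   [truth_as_calls]); e.g. `c(C3 = -3.2)` plants a 3.2-point loss in clade-3
#'   homozygotes on an IQ-like scale.
#' @param expression_effects named numeric vector: per-allele-copy additive
#'   shift of log-expression for target genes.
#' @param covariate_effects named numeric vector of linear covariate
#'   coefficients (names must match covariate columns).
#' @param noise_sd residual standard deviation (default 15, the IQ convention).
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(recessive_effects = numeric(),
                        expression_effects = numeric(),
                        covariate_effects = numeric(),
                        noise_sd = 15) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(recessive_effects = recessive_effects,
                 expression_effects = expression_effects,
                 covariate_effects = covariate_effects,
                 noise_sd = noise_sd),
            class = "effect_spec")
}

#' Simulate quantitative phenotypes with recessive clade effects
#'
#' Generates `y = 100 + sum_clades effect * [homozygous for clade] +
#' covariates + Normal(0, noise_sd)`, i.e. an IQ-like scale (mean 100, SD 15
#' by default).
#'
#' @param truth `truth_labels` from [simulate_locus] (or a data.frame with
#'   `sample_id`, `allele1`, `allele2` integer clades).
#' @param spec an [effect_spec]; `recessive_effects` names must be `C<k>`
#'   clades present in the truth.
#' @param covariates optional data.frame aligned to samples (columns matching
#'   `spec$covariate_effects` names are used).
#' @param seed RNG seed.
#' @return data.frame `sample_id`, `phenotype`, plus any covariate columns.
#' @export
simulate_phenotypes <- function(truth, spec, covariates = NULL, seed = NULL) {
  stopifnot(inherits(spec, "effect_spec"))
  dip <- if (inherits(truth, "truth_labels")) truth$diplotype else truth
  n <- nrow(dip)
  k_max <- max(dip$allele1, dip$allele2)
  eff <- spec$recessive_effects
  if (length(eff)) {
    clade_idx <- as.integer(sub("^C", "", names(eff)))
    if (any(is.na(clade_idx)) || any(clade_idx < 1) || any(clade_idx > k_max))
      stop("unknown clade in recessive_effects: ",
           paste(names(eff)[is.na(clade_idx) | clade_idx > k_max], collapse = ", "))
  }
  with_seed(seed, {
    y <- rep(100, n)
    for (i in seq_along(eff)) {
      ci <- as.integer(sub("^C", "", names(eff)[i]))
      hom <- dip$allele1 == ci & dip$allele2 == ci
      y[hom] <- y[hom] + eff[i]
    }
    if (!is.null(covariates) && length(spec$covariate_effects)) {
      for (cv in names(spec$covariate_effects)) {
        if (!cv %in% names(covariates))
          stop("covariate column not found: ", cv)
        y <- y + spec$covariate_effects[[cv]] * covariates[[cv]]
      }
    }
    y <- y + stats::rnorm(n, 0, spec$noise_sd)
    out <- data.frame(sample_id = dip$sample_id, phenotype = y,
                      stringsAsFactors = FALSE)
    if (!is.null(covariates)) out <- cbind(out, covariates)
    out
  })
}

#' Simulate clinal population allele frequencies
#'
#' Frequencies follow a logistic cline in distance with Gaussian drift noise
#' on the logit scale:
#' `freq_k = plogis(qlogis(base_freq) + slope * distance_k / 1000 + N(0, drift_sd))`.
#'
#' @param distances_km non-negative distances of each population from the
#'   origin.
#' @param base_freq frequency at distance 0, in (0, 1).
#' @param slope_per_1000km logit-scale slope per 1000 km.
#' @param drift_sd SD of logit-scale drift noise.
#' @param n_samples per-population sample size recorded in the table.
#' @param seed RNG seed.
#' @return a [population_table] with columns `pop_code`, `n_samples`,
#'   `distance_km`, `allele_freq`.
#' @export
simulate_clinal_frequencies <- function(distances_km, base_freq,
                                        slope_per_1000km = 0, drift_sd = 0,
                                        n_samples = 100, seed = NULL) {
  if (any(distances_km < 0)) stop("distances must be non-negative")
  if (base_freq <= 0 || base_freq >= 1) stop("base_freq must be in (0, 1)")
  with_seed(seed, {
    logit <- stats::qlogis(base_freq) +
      slope_per_1000km * distances_km / 1000 +
      stats::rnorm(length(distances_km), 0, drift_sd)
    freq <- stats::plogis(logit)
    population_table(data.frame(
      pop_code = sprintf("POP%02d", seq_along(distances_km)),
      n_samples = n_samples,
      distance_km = distances_km,
      allele_freq = freq, stringsAsFactors = FALSE))
  })
}

#' Simulate a gene-expression table with additive allele effects
#'
#' Log-expression of each gene is `baseline + sum_clades dose(clade) * effect
#' + Normal(0, noise_sd)`; only genes named in `target_effects` carry nonzero
#' effects, all others are pure noise.
#'
#' @param truth `truth_labels` (or diplotype data.frame as in
#'   [simulate_phenotypes]).
#' @param n_genes number of genes (default 11, a typical cis-region gene
#'   count).
#' @param target_effects named list: `list(gene3 = c(C1 = 0.5))` plants a
#'   +0.5 log-unit shift per clade-1 allele copy on gene 3. Gene names must be
#'   among `gene1..gene<n_genes>`.
#' @param baseline baseline log-expression (default 8).
#' @param noise_sd residual SD on the log scale (default 0.5).
#' @param seed RNG seed.
#' @return numeric matrix, genes x samples, dimnames set.
#' @export
simulate_expression <- function(truth, n_genes = 11, target_effects = list(),
                                baseline = 8, noise_sd = 0.5, seed = NULL) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  dip <- if (inherits(truth, "truth_labels")) truth$diplotype else truth
  n <- nrow(dip)
  gene_ids <- paste0("gene", seq_len(n_genes))
  bad <- setdiff(names(target_effects), gene_ids)
  if (length(bad)) stop("unknown target gene(s): ", paste(bad, collapse = ", "))
  k_max <- max(dip$allele1, dip$allele2)
  with_seed(seed, {
    expr <- matrix(baseline + stats::rnorm(n_genes * n, 0, noise_sd),
                   nrow = n_genes,
                   dimnames = list(gene_ids, dip$sample_id))
    for (g in names(target_effects)) {
      eff <- target_effects[[g]]
      clade_idx <- as.integer(sub("^C", "", names(eff)))
      if (any(is.na(clade_idx)) || any(clade_idx > k_max))
        stop("unknown clade in expression effects for ", g)
      for (i in seq_along(eff)) {
        dose <- (dip$allele1 == clade_idx[i]) + (dip$allele2 == clade_idx[i])
        expr[g, ] <- expr[g, ] + eff[i] * dose
      }
    }
    expr
  })
}

#' Build an outgroup haplotype from a founder clade
#'
#' Takes a founder clade's block haplotype and adds private mutations at
#' uniformly chosen sites, giving a sequence unambiguously nearest to its
#' source clade -- the construction used for outgroup-rooting tests.
#'
#' @param founders clade x site founder matrix (from `truth$founders`).
#' @param clade source clade index (default 2).
#' @param n_private number of private mutations.
#' @param seed RNG seed.
#' @return integer 0/1 vector.
#' @export
make_outgroup <- function(founders, clade = 2, n_private = 5, seed = NULL) {
  stopifnot(clade >= 1, clade <= nrow(founders))
  with_seed(seed, {
    out <- founders[clade, ]
    sites <- sample.int(ncol(founders), n_private)
    out[sites] <- 1L - out[sites]
    as.integer(out)
  })
}
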