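# hapblocks

Detection, calling and analysis of **extended haplotype-genotype blocks** in
phased SNP data.

## The problem

Regions harbouring inversion polymorphisms or other recombination-suppressing
structural variation can transmit megabase-scale SNP segments as units. Such a
region behaves like one multi-allelic locus: each individual carries an
unordered pair of block alleles (its *diplotype*), the alleles form deeply
diverged clades with ancient coalescence, they follow Hardy–Weinberg
proportions, show strong population stratification consistent with serial
founder effects, and can be tagged by single SNPs in high LD. Characterizing
these blocks — and testing whether diplotypes associate with quantitative
phenotypes or local gene expression — requires a chain of specialized steps
that `hapblocks` packages end to end, for statistical geneticists working with
phased cohort or consortium data.

## What the package computes

1. **Detection** (`scan_region`). For each candidate segment `[b1, b2]` every
   chromosome is reduced to the pair of *k*-SNP local haplotype words just
   inside the two ends. A two-component mixture of independent left/right
   multinomials (M1) is compared with a single independence component (M0) by

   `ΔBIC = BIC(M0) − BIC(M1)`, `BIC = −2 ℓ + p·log n`,

   `ΔBIC > 0` indicating that some chromosomes carry unusually high linkage
   between the distant points — the imprint of a block inherited as a unit.
   Overlapping positive windows merge into candidate segments.
2. **Calling** (`call_diplotypes`). Classical MDS of genotype-dosage distances
   within a segment, k-means with `k = a(a+1)/2` clusters for `a` alleles, and
   geometric labelling: extreme clusters are homozygotes, clusters nearest the
   midpoint of two homozygote centroids are their heterozygote. A 1-D
   fallback (`call_1d_fallback`) handles sparse tag-SNP panels, inferring the
   third allele's homozygotes as double non-carriers.
3. **Trio validation** (`mendelian_error_rate`, `tdt`). Mendelian-consistency
   rate of calls in trios, and the per-allele transmission disequilibrium test
   `χ² = (b − c)²/(b + c)` over heterozygous parents.
4. **Population genetics** (`discover_tag_snps`, `hwe_test`, `fst_two_level`,
   `recomb_rate_permutation_test`, `clinal_permutation_test`,
   `neighbor_joining`, `assign_outgroup`). Tag SNPs at `r² > 0.9`,
   Hardy–Weinberg screening, Weir–Cockerham FST, permutation nulls for
   recombination-rate reduction and for clinal frequency–distance R² against
   frequency-matched genomic SNPs (empirical p always `(k+1)/(n+1)`), and
   Hamming-distance NJ phylogenies with outgroup assignment.
5. **Association** (`fit_gaussian_model`, `meta_fixed_effects`, `eqtl_scan`).
   OLS of (standardized, mean 100 / SD 15) phenotypes on additive or
   recessive dosages with covariates; inverse-variance fixed-effects pooling
   with Cochran's Q heterogeneity; Bonferroni-controlled cis-expression scans.
6. **Synthetic data** (`simulate_locus`, `simulate_trios`,
   `simulate_phenotypes`, `simulate_expression`,
   `simulate_clinal_frequencies`). Truth-labelled generators with the block
   structure above, so every stage is testable without external downloads.

Standard formats are supported throughout: phased VCF in, 3-column pedigree
TSV / PLINK FAM, HapMap-style recombination rate files, TSV tables, Newick
out.

## Worked example

```r
library(hapblocks)

# 1. simulate a locus: 500 individuals, 3 clades at 0.59/0.24/0.17
sim <- simulate_locus(locus_config(n_individuals = 500, seed = 42))
sim$genotypes
#> genotype_matrix: 500 samples, 800 variants on chromosome(s) 15

# 2. scan for extended-haplotype segments
scan <- scan_region(sim$genotypes, window_sizes_bp = c(100000, 150000), seed = 1)
scan
#> scan_result: 27 windows, 5 positive, 1 merged segment(s)
#>   start_bp end_bp max_bic_diff n_windows
#> 1   301000 501000     953.3237         5

# 3. call diplotypes inside the detected segment
seg <- scan$segments[which.max(scan$segments$max_bic_diff), ]
model <- call_diplotypes(sim$genotypes, region = c(seg$start_bp, seg$end_bp),
                         n_alleles = 3, seed = 2)
model
#> cluster_model: 6 clusters -> H1/H1 H1/H2 H2/H3 H2/H2 H1/H3 H3/H3
#> allele frequencies: H1=0.608 H2=0.227 H3=0.165
diplotype_accuracy(model$calls, truth_as_calls(sim$truth))$accuracy
#> [1] 1

# 4. trio validation
tr <- simulate_trios(sim$genotypes, n_trios = 200, error_rate = 0,
                     seed = 3, truth = sim$truth)
trio_model <- call_diplotypes(tr$genotypes, region = c(seg$start_bp, seg$end_bp),
                              n_alleles = 3, seed = 4)
mendelian_error_rate(trio_model$calls, tr$pedigree)$rate
#> [1] 0
tdt(trio_model$calls, tr$pedigree, "H1")
#> TDT H1: b = 101, c = 88, chi-square = 0.8942, p = 0.3443

# 5. recessive association and meta-analysis
ph <- simulate_phenotypes(sim$truth,
                          effect_spec(recessive_effects = c(C1 = -2.4),
                                      noise_sd = 15), seed = 5)
dose <- encode_dosage(truth_as_calls(sim$truth), "C1", "recessive")
fit <- fit_gaussian_model(ph$phenotype, dose)
fit
#>   cohort allele model      beta       se         p   n
#> 1   <NA>   <NA>  <NA> -2.095888 1.399242 0.1347997 500
meta_fixed_effects(c(fit$beta, -2.1), c(fit$se, 1.4))
#> fixed-effects meta-analysis (k = 2): beta = -2.0979 (se 0.9897), z = -2.120, p = 0.03402
#> heterogeneity: Q = 0.0000 on 1 df, p = 0.9983
```

Reading the output: the scan localizes the planted suppressed-recombination
block (true extent 301–500 kb) with a strongly positive BIC difference; the
six MDS clusters are labelled as the three homozygote and three heterozygote
diplotypes, with allele frequencies recovering the planted 0.59/0.24/0.17;
error-free trios give a Mendelian error rate of exactly 0 and a null TDT; a
planted −2.4-point recessive effect (on an IQ-like SD-15 scale) is estimated
with the wide standard error a ~3%-homozygote class implies, and pooling a
second cohort sharpens it to nominal significance with no heterogeneity.

The methods vignette (`vignettes/hapblocks-methods.Rmd`) documents the models,
parameter defaults, numerical conventions and the generator's scope.

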