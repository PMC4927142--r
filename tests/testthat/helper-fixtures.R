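# Shared fixtures, built in code at test time.

# A tiny phased genotype matrix: 2 samples, 3 SNPs.
toy_gm <- function() {
  genotype_matrix(
    c("s1", "s2"),
    data.frame(chrom = "15", pos = c(100L, 200L, 300L),
               id = c("rs1", "rs2", "rs3"), ref = c("A", "C", "G"),
               alt = c("G", "T", "A"), stringsAsFactors = FALSE),
    matrix(c(0L, 1L, 0L,
             1L, 0L, 1L,
             0L, 0L, 1L,
             1L, 1L, NA), nrow = 4, byrow = TRUE)
  )
}

# Write a small phased VCF to a temp file and return the path.
toy_vcf <- function(lines = NULL) {
  path <- tempfile(fileext = ".vcf")
  if (is.null(lines)) {
    lines <- c(
      "##fileformat=VCFv4.2",
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
      "15\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
      "15\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|0\t0|1",
      "15\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t1|0\t0|0"
    )
  }
  writeLines(lines, path)
  path
}

# The default simulated locus used across calling/trio tests (cached per run).
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_locus(locus_config(n_individuals = 400, seed = 101))
    cache
  }
})

block_region <- function(sim) {
  pos <- sim$genotypes$variants$pos[sim$truth$block_cols]
  c(min(pos), max(pos))
}

# Simulate diplotype calls for trio sets directly at the call level
# (parents drawn from HWE, children by fair transmission): the null model
# of the transmission disequilibrium test.
simulate_null_trio_calls <- function(n_trios, freqs = c(0.5, 0.3, 0.2)) {
  alleles <- paste0("H", seq_along(freqs))
  draw <- function(n) matrix(sample(alleles, 2 * n, replace = TRUE, prob = freqs),
                             ncol = 2)
  fa <- draw(n_trios); mo <- draw(n_trios)
  pick <- function(m) m[cbind(seq_len(nrow(m)), sample(1:2, nrow(m), TRUE))]
  ch <- cbind(pick(fa), pick(mo))
  ids <- function(prefix) paste0(prefix, seq_len(n_trios))
  calls <- diplotype_calls(
    data.frame(
      sample_id = c(ids("f"), ids("m"), ids("c")),
      allele1 = c(pmin(fa[, 1], fa[, 2]), pmin(mo[, 1], mo[, 2]),
                  pmin(ch[, 1], ch[, 2])),
      allele2 = c(pmax(fa[, 1], fa[, 2]), pmax(mo[, 1], mo[, 2]),
                  pmax(ch[, 1], ch[, 2])),
      stringsAsFactors = FALSE),
    alleles = alleles)
  ped <- pedigree_table(data.frame(child = ids("c"), father = ids("f"),
                                   mother = ids("m"), stringsAsFactors = FALSE))
  list(calls = calls, ped = ped)
}

# A recombination map with i.i.d. log-normal interval rates and a cumulative
# column consistent with the rates (so interpolation of cum_cM is an
# independent oracle for mean rates).
random_rate_map <- function(n_intervals = 60, spacing_bp = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- seq(1, by = spacing_bp, length.out = n_intervals + 1)
  rate <- stats::rlnorm(n_intervals + 1, meanlog = 0, sdlog = 1)
  cum <- c(0, cumsum(rate[-length(rate)] * diff(pos) / 1e6))
  recombination_map(data.frame(pos = pos, rate_cM_Mb = rate, cum_cM = cum))
}
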