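#' Construct a phased genotype matrix
#'
#' The central container of the package: phased biallelic SNP alleles with two
#' haplotype rows per sample. Rows `2i - 1` and `2i` of `alleles` are the two
#' phased chromosomes of sample `i`, in the phase order of the source data.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param variants data.frame with columns `chrom`, `pos` (1-based bp, strictly
#'   increasing within a chromosome), `id`, `ref`, `alt`.
#' @param alleles integer matrix of 0/1/`NA` with `2 * length(sample_ids)` rows
#'   and `nrow(variants)` columns.
#' @param pop_labels optional character vector of per-sample population codes.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `sample_ids`, `variants`, `alleles`, `pop_labels`.
#' @examples
#' gm <- genotype_matrix(
#'   c("s1", "s2"),
#'   data.frame(chrom = "15", pos = c(100L, 200L), id = c("a", "b"),
#'              ref = "A", alt = "G"),
#'   matrix(c(0L, 1L, 0L, 1L, 1L, 0L, 0L, 1L), nrow = 4)
#' )
#' n_samples(gm)
#' @export
genotype_matrix <- function(sample_ids, variants, alleles, pop_labels = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  variants <- as.data.frame(variants)
  required <- c("chrom", "pos", "id", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols))
    stop("variants is missing column(s): ", paste(missing_cols, collapse = ", "))
  variants$pos <- as.integer(variants$pos)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != 2L * length(sample_ids))
    stop("alleles must have exactly two haplotype rows per sample")
  if (ncol(alleles) != nrow(variants))
    stop("alleles column count must match the number of variants")
  bad <- alleles[!is.na(alleles)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("every non-missing allele must be 0 or 1")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (!is.null(pop_labels)) {
    pop_labels <- as.character(pop_labels)
    if (length(pop_labels) != length(sample_ids))
      stop("pop_labels must have one entry per sample")
  }
  structure(
    list(sample_ids = sample_ids, variants = variants,
         alleles = alleles, pop_labels = pop_labels),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples,",
      nrow(x$variants), "variants on chromosome(s)",
      paste(unique(x$variants$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / variants in a genotype matrix
#' @param gm a [genotype_matrix].
#' @return integer count.
#' @export
n_samples <- function(gm) length(gm$sample_ids)

#' @rdname n_samples
#' @export
n_variants <- function(gm) nrow(gm$variants)

#' Per-sample genotype dosage matrix
#'
#' Sums the two phased haplotype rows of each sample into an alternate-allele
#' dosage in 0/1/2. A dosage involving a missing allele is `NA` (missingness
#' propagates; nothing is imputed).
#'
#' @param gm a [genotype_matrix].
#' @return numeric matrix, samples x variants, rownames = sample ids.
#' @export
dosage_matrix <- function(gm) {
  n <- n_samples(gm)
  h1 <- gm$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  h2 <- gm$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  d <- h1 + h2
  rownames(d) <- gm$sample_ids
  colnames(d) <- gm$variants$id
  d
}

#' Subset a genotype matrix to a genomic region
#'
#' @param gm a [genotype_matrix].
#' @param region either a string `"chrom:start-end"` or a numeric
#'   `c(start, end)`; coordinates are 1-based inclusive.
#' @return a [genotype_matrix] restricted to variants inside the region.
#' @export
subset_region <- function(gm, region) {
  if (is.character(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L)
      stop("region must look like 'chrom:start-end', got: ", region)
    keep <- gm$variants$chrom == m[2] &
      gm$variants$pos >= as.integer(m[3]) & gm$variants$pos <= as.integer(m[4])
  } else {
    if (length(region) != 2L || region[1] > region[2])
      stop("numeric region must be c(start, end) with start <= end")
    keep <- gm$variants$pos >= region[1] & gm$variants$pos <= region[2]
  }
  genotype_matrix(gm$sample_ids, gm$variants[keep, , drop = FALSE],
                  gm$alleles[, keep, drop = FALSE], gm$pop_labels)
}

#' Remove variants below a minor-allele-frequency threshold
#'
#' MAF is computed over non-missing alleles only. The conventional screening
#' threshold for this kind of analysis is 0.01.
#'
#' @param gm a [genotype_matrix].
#' @param threshold MAF cutoff in `[0, 0.5]`; variants with MAF strictly below
#'   it are removed.
#' @return filtered [genotype_matrix].
#' @export
filter_by_maf <- function(gm, threshold = 0.01) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 0.5)
    stop("threshold must be in [0, 0.5]")
  f <- colMeans(gm$alleles, na.rm = TRUE)
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0          # all-missing column: treat as monomorphic
  keep <- maf >= threshold
  if (!any(keep))
    stop("all variants removed by MAF filter; reduce the threshold")
  genotype_matrix(gm$sample_ids, gm$variants[keep, , drop = FALSE],
                  gm$alleles[, keep, drop = FALSE], gm$pop_labels)
}

#' Read phased genotypes from a VCF file
#'
#' Retains only biallelic SNPs (single-base REF and ALT). Multi-allelic
#' records are dropped, not split, with a message reporting the count. The GT
#' field of each sample becomes two haplotype rows, preserving phase order;
#' `.` alleles become `NA`.
#'
#' @param path VCF file (plain or bgzipped).
#' @param region optional `"chrom:start-end"` filter, 1-based inclusive on POS.
#' @param phase_required if `TRUE` (default) an unphased separator `/` in any
#'   retained record is an error naming the first offending record; if
#'   `FALSE`, unphased genotypes are accepted with arbitrary phase order.
#' @return a [genotype_matrix].
#' @export
read_phased_vcf <- function(path, region = NULL, phase_required = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no records in VCF: ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("GT field absent in VCF: ", path)

  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_multi <- sum(grepl(",", fix$ALT, fixed = TRUE))
  if (n_multi > 0L)
    message("read_phased_vcf: skipped ", n_multi, " multi-allelic record(s)")
  fix <- fix[snp, , drop = FALSE]
  gt <- gt[snp, , drop = FALSE]
  if (nrow(fix) == 0L) stop("no biallelic SNPs retained from ", path)

  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) stop("region must look like 'chrom:start-end'")
    keep <- fix$CHROM == m[2] & as.integer(fix$POS) >= as.integer(m[3]) &
      as.integer(fix$POS) <= as.integer(m[4])
    fix <- fix[keep, , drop = FALSE]
    gt <- gt[keep, , drop = FALSE]
    if (nrow(fix) == 0L) stop("no variants in region ", region)
  }

  if (phase_required) {
    unphased <- matrix(grepl("/", gt, fixed = TRUE), nrow = nrow(gt))
    if (any(unphased)) {
      idx <- which(unphased, arr.ind = TRUE)[1, ]
      stop("unphased genotype '", gt[idx[1], idx[2]], "' at ",
           fix$CHROM[idx[1]], ":", fix$POS[idx[1]], " (",
           fix$ID[idx[1]], ") for sample ", colnames(gt)[idx[2]])
    }
  }

  samples <- colnames(gt)
  n <- length(samples)
  m <- nrow(fix)
  alleles <- matrix(NA_integer_, nrow = 2L * n, ncol = m)
  parse_one <- function(g) {
    # "0|1", "0/1", ".|.", "." -> c(a1, a2)
    if (is.na(g) || g == ".") return(c(NA_integer_, NA_integer_))
    parts <- strsplit(g, "[|/]")[[1]]
    if (length(parts) == 1L) parts <- c(parts, NA_character_)
    suppressWarnings(as.integer(ifelse(parts == ".", NA_character_, parts)))
  }
  for (j in seq_len(n)) {
    parsed <- vapply(gt[, j], parse_one, integer(2), USE.NAMES = FALSE)
    alleles[2L * j - 1L, ] <- parsed[1L, ]
    alleles[2L * j, ] <- parsed[2L, ]
  }
  bad <- alleles[!is.na(alleles)]
  if (length(bad) && any(!bad %in% c(0L, 1L)))
    stop("allele index other than 0/1 in biallelic record; malformed GT")

  ord <- order(fix$CHROM, as.integer(fix$POS))
  fix <- fix[ord, , drop = FALSE]
  alleles <- alleles[, ord, drop = FALSE]
  genotype_matrix(
    samples,
    data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
               id = ifelse(is.na(fix$ID) | fix$ID == ".",
                           paste0(fix$CHROM, ":", fix$POS), fix$ID),
               ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE),
    alleles
  )
}

#' Write a genotype matrix as a phased VCF
#'
#' Emits a minimal VCF 4.2 with phased GT fields; the exact inverse of
#' [read_phased_vcf] on its own output.
#'
#' @param gm a [genotype_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(gm, path) {
  n <- n_samples(gm)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hapblocks",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")
  )
  h1 <- gm$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  h2 <- gm$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  fmt <- function(x) ifelse(is.na(x), ".", as.character(x))
  lines <- vapply(seq_len(n_variants(gm)), function(j) {
    gts <- paste0(fmt(h1[, j]), "|", fmt(h2[, j]))
    paste(c(gm$variants$chrom[j], gm$variants$pos[j], gm$variants$id[j],
            gm$variants$ref[j], gm$variants$alt[j], ".", "PASS", ".", "GT",
            gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}
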