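#' Mendelian consistency of diplotype calls in trios
#'
#' A trio errs iff the child's unordered allele pair cannot be formed by
#' taking one allele from each parent. Trios with any member uncalled or
#' missing are excluded from the denominator.
#'
#' @param calls a [diplotype_calls] object covering children and parents.
#' @param ped a [pedigree_table].
#' @return list with `rate` (errors / evaluable trios), `flags` (data.frame
#'   `child`, `consistent`), `n_evaluable`.
#' @export
mendelian_error_rate <- function(calls, ped) {
  lookup <- function(ids) {
    idx <- match(ids, calls$sample_id)
    cbind(calls$allele1[idx], calls$allele2[idx])
  }
  ch <- lookup(ped$child); fa <- lookup(ped$father); mo <- lookup(ped$mother)
  evaluable <- stats::complete.cases(ch) & stats::complete.cases(fa) &
    stats::complete.cases(mo)
  if (!any(evaluable)) stop("zero evaluable trios")
  c1f <- ch[, 1] == fa[, 1] | ch[, 1] == fa[, 2]
  c2f <- ch[, 2] == fa[, 1] | ch[, 2] == fa[, 2]
  c1m <- ch[, 1] == mo[, 1] | ch[, 1] == mo[, 2]
  c2m <- ch[, 2] == mo[, 1] | ch[, 2] == mo[, 2]
  consistent <- (c1f & c2m) | (c2f & c1m)
  consistent[!evaluable] <- NA
  errs <- sum(!consistent[evaluable])
  list(rate = errs / sum(evaluable),
       flags = data.frame(child = ped$child, consistent = consistent,
                          stringsAsFactors = FALSE),
       n_evaluable = sum(evaluable))
}

#' Transmission disequilibrium test for one block allele
#'
#' The multi-allelic calls are folded to carrier / non-carrier of the target
#' allele. Over parents heterozygous for the target (carrier dose exactly 1),
#' `b` counts transmissions of the allele to the child and `c`
#' non-transmissions; `chi_square = (b - c)^2 / (b + c)` with 1 df.
#' Mendelian-inconsistent trios are excluded; both parents of a trio
#' contribute independently when heterozygous; homozygous parents are
#' uninformative. Transmissions are resolved by dose accounting: the target
#' copies a child carries beyond those contributed by target-homozygous
#' parents must come from heterozygous parents.
#'
#' @param calls a [diplotype_calls] object.
#' @param ped a [pedigree_table].
#' @param allele target allele name (must be in the declared allele set).
#' @return list of class `tdt_result`: `allele`, `b`, `c`, `chi_square`,
#'   `p_value`, `undefined` (TRUE when `b + c = 0`).
#' @export
tdt <- function(calls, ped, allele) {
  if (!allele %in% allele_set(calls))
    stop("allele not in declared set: ", allele)
  mend <- mendelian_error_rate(calls, ped)
  use <- which(mend$flags$consistent %in% TRUE)
  dose <- function(ids) {
    idx <- match(ids, calls$sample_id)
    (calls$allele1[idx] == allele) + (calls$allele2[idx] == allele)
  }
  dc <- dose(ped$child[use])
  df_ <- dose(ped$father[use])
  dm <- dose(ped$mother[use])
  h <- (df_ == 1) + (dm == 1)          # informative (heterozygous) parents
  hom <- (df_ == 2) + (dm == 2)        # obligate transmitters
  trans <- pmin(pmax(dc - hom, 0), h)  # target copies from het parents
  b <- sum(trans)
  c_ <- sum(h - trans)
  if (b + c_ == 0) {
    res <- list(allele = allele, b = b, c = c_, chi_square = NA_real_,
                p_value = NA_real_, undefined = TRUE)
  } else {
    chi <- (b - c_)^2 / (b + c_)
    res <- list(allele = allele, b = b, c = c_, chi_square = chi,
                p_value = stats::pchisq(chi, 1, lower.tail = FALSE),
                undefined = FALSE)
  }
  class(res) <- "tdt_result"
  res
}

#' @export
print.tdt_result <- function(x, ...) {
  cat(sprintf("TDT %s: b = %d, c = %d, chi-square = %s, p = %s%s\n",
              x$allele, x$b, x$c,
              format(x$chi_square, digits = 4),
              format(x$p_value, digits = 4),
              if (x$undefined) " (undefined: no informative parents)" else ""))
  invisible(x)
}
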