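#' Encode diplotype calls as a genetic-model dosage
#'
#' Additive coding counts copies of the target allele (0/1/2); recessive
#' coding is the indicator of homozygosity for the target allele
#' (homozygote-vs-rest contrast). Uncalled samples get `NA`.
#'
#' @param calls a [diplotype_calls] object.
#' @param allele target allele.
#' @param model `"additive"` or `"recessive"`.
#' @return named numeric vector (names = sample ids).
#' @export
encode_dosage <- function(calls, allele, model = c("additive", "recessive")) {
  model <- match.arg(model)
  if (!allele %in% allele_set(calls))
    stop("allele not in declared set: ", allele)
  dose <- (calls$allele1 == allele) + (calls$allele2 == allele)
  out <- if (model == "additive") as.numeric(dose)
         else as.numeric(dose == 2)
  stats::setNames(out, calls$sample_id)
}

#' Standardize scores to mean 100, SD 15
#'
#' The conventional IQ scale. Affine (hence order-preserving) and idempotent.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return standardized vector.
#' @export
standardize_scores <- function(values) {
  ok <- !is.na(values)
  if (length(unique(values[ok])) < 2L)
    stop("cannot standardize a constant input")
  (values - mean(values, na.rm = TRUE)) / stats::sd(values, na.rm = TRUE) *
    15 + 100
}

#' Gaussian regression of a phenotype on a genetic dosage
#'
#' Ordinary least squares `y ~ dosage + covariates`; the reported beta, SE and
#' two-sided p-value (t reference with residual df) are for the dosage term.
#' Collinear covariate columns are dropped with a warning; a rank deficiency
#' involving the dosage itself is an error. Rows with any missing value are
#' dropped.
#'
#' @param y numeric outcome.
#' @param dosage numeric genetic dosage (from [encode_dosage]).
#' @param covariates optional data.frame / matrix of covariate columns
#'   (supplied as-is; e.g. sex, age, ancestry principal components).
#' @param cohort,allele,model optional metadata echoed into the result.
#' @return one-row data.frame of class `association_result`: `cohort`,
#'   `allele`, `model`, `beta`, `se`, `p`, `n`.
#' @export
fit_gaussian_model <- function(y, dosage, covariates = NULL,
                               cohort = NA_character_, allele = NA_character_,
                               model = NA_character_) {
  dat <- data.frame(y = y, dosage = dosage)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  fit <- stats::lm(y ~ ., data = dat)
  coefs <- stats::coef(fit)
  if (is.na(coefs["dosage"]))
    stop("design is rank deficient in the dosage column")
  dropped <- names(coefs)[is.na(coefs)]
  if (length(dropped))
    warning("collinear covariate(s) dropped: ", paste(dropped, collapse = ", "))
  sm <- summary(fit)$coefficients
  out <- data.frame(cohort = cohort, allele = allele, model = model,
                    beta = sm["dosage", "Estimate"],
                    se = sm["dosage", "Std. Error"],
                    p = sm["dosage", "Pr(>|t|)"],
                    n = nrow(dat), stringsAsFactors = FALSE)
  class(out) <- c("association_result", "data.frame")
  out
}

#' Inverse-variance fixed-effects meta-analysis
#'
#' Pools per-cohort estimates with weights `w = 1 / se^2`:
#' `pooled = sum(w * beta) / sum(w)`, `pooled_se = 1 / sqrt(sum(w))`, z-test
#' against the normal reference. Heterogeneity is Cochran's
#' `Q = sum(w * (beta - pooled)^2)` on `k - 1` df (undefined and flagged for a
#' single study).
#'
#' @param betas per-study effect estimates.
#' @param ses per-study standard errors (> 0).
#' @return list of class `meta_result`: `pooled_beta`, `pooled_se`, `z`, `p`,
#'   `Q`, `df`, `p_heterogeneity`, `weights`, `k`.
#' @export
meta_fixed_effects <- function(betas, ses) {
  if (length(betas) != length(ses) || length(betas) < 1L)
    stop("need >= 1 study with matching betas and ses")
  if (any(ses <= 0)) stop("all standard errors must be > 0")
  w <- 1 / ses^2
  pooled <- sum(w * betas) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- pooled / pooled_se
  k <- length(betas)
  Q <- sum(w * (betas - pooled)^2)
  df <- k - 1L
  p_het <- if (df >= 1L) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_
  structure(list(pooled_beta = pooled, pooled_se = pooled_se, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 Q = if (df >= 1L) Q else NA_real_, df = df,
                 p_heterogeneity = p_het, weights = w, k = k),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("fixed-effects meta-analysis (k = %d): beta = %.4f (se %.4f), z = %.3f, p = %s\n",
              x$k, x$pooled_beta, x$pooled_se, x$z, format(x$p, digits = 4)))
  if (x$df >= 1L)
    cat(sprintf("heterogeneity: Q = %.4f on %d df, p = %s\n",
                x$Q, x$df, format(x$p_heterogeneity, digits = 4)))
  else cat("heterogeneity undefined (single study)\n")
  invisible(x)
}

#' cis-expression scan over genes with Bonferroni control
#'
#' Fits one regression per gene of (log-)expression on the allele dosage, and
#' flags genes passing the region-wide Bonferroni threshold
#' `alpha / n_genes_tested` (for the conventional 11-gene cis region and
#' `alpha = 0.05` this is 0.05 / 11 = 4.5e-3). Genes with zero expression
#' variance are skipped with a warning.
#'
#' @param expression genes x samples numeric matrix (log scale unless
#'   `log_transform = TRUE`).
#' @param calls a [diplotype_calls] object; samples are matched by column
#'   name.
#' @param allele target allele.
#' @param model `"additive"` or `"recessive"`.
#' @param alpha family-wise error rate (default 0.05).
#' @param covariates optional covariate data.frame aligned to the expression
#'   columns.
#' @param log_transform log-transform the expression first (default `FALSE`;
#'   expression is analyzed on the log scale).
#' @return data.frame `gene`, `beta`, `se`, `p`, `n`, `significant`, with
#'   attribute `bonferroni_threshold`.
#' @export
eqtl_scan <- function(expression, calls, allele,
                      model = c("additive", "recessive"), alpha = 0.05,
                      covariates = NULL, log_transform = FALSE) {
  model <- match.arg(model)
  expression <- as.matrix(expression)
  if (log_transform) expression <- log(expression)
  dosage <- encode_dosage(calls, allele, model)
  idx <- match(colnames(expression), names(dosage))
  if (anyNA(idx))
    stop("expression columns missing from calls: ",
         paste(utils::head(colnames(expression)[is.na(idx)], 5), collapse = ", "))
  dosage <- dosage[idx]

  rows <- list()
  skipped <- character(0)
  for (g in rownames(expression)) {
    yg <- expression[g, ]
    if (stats::sd(yg, na.rm = TRUE) == 0) {
      skipped <- c(skipped, g)
      next
    }
    fit <- fit_gaussian_model(yg, dosage, covariates, allele = allele,
                              model = model)
    rows[[g]] <- data.frame(gene = g, beta = fit$beta, se = fit$se,
                            p = fit$p, n = fit$n, stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped zero-variance gene(s): ", paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable genes")
  threshold <- alpha / nrow(out)
  out$significant <- out$p < threshold
  rownames(out) <- NULL
  attr(out, "bonferroni_threshold") <- threshold
  out
}
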