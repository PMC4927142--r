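#' Encode local haplotypes adjacent to a candidate breakpoint
#'
#' The code of a chromosome is the word formed by the `k` SNP alleles
#' immediately left (positions `<= breakpoint_pos`) or right (positions
#' `> breakpoint_pos`) of the breakpoint, mapped to a dense integer alphabet.
#' Chromosomes with a missing allele in any of the `k` sites get code `NA`.
#'
#' @param gm a [genotype_matrix].
#' @param breakpoint_pos breakpoint position in bp.
#' @param side `"left"` or `"right"`.
#' @param k number of SNPs in the block (default 2).
#' @return integer vector of codes (length = number of chromosome rows), with
#'   attribute `words` giving the allele word of each code.
#' @export
encode_local_haplotypes <- function(gm, breakpoint_pos, side = c("left", "right"),
                                    k = 2) {
  side <- match.arg(side)
  pos <- gm$variants$pos
  idx <- if (side == "left") which(pos <= breakpoint_pos)
         else which(pos > breakpoint_pos)
  if (length(idx) < k)
    stop("fewer than k = ", k, " SNPs on the ", side,
         " side of position ", breakpoint_pos)
  idx <- if (side == "left") utils::tail(idx, k) else utils::head(idx, k)
  block <- gm$alleles[, idx, drop = FALSE]
  val <- as.vector(block %*% 2^(seq_len(k) - 1L))   # NA propagates
  f <- factor(val)
  codes <- as.integer(f)
  attr(codes, "words") <- vapply(as.integer(levels(f)), function(v)
    paste(as.integer(intToBits(v))[seq_len(k)], collapse = ""), character(1))
  codes
}

#' Fit independence and two-component mixture models to paired block codes
#'
#' Compares a null model M0 -- a single component in which the left and right
#' local-haplotype codes are independent multinomials -- against M1, a
#' two-component mixture whose components are each independent left/right
#' multinomial pairs. M1 captures the situation where the chromosomes of some
#' individuals carry higher SNP-block linkage between the two points than
#' expected under independence (the imprint of a segment transmitted as a
#' unit). The comparison statistic is
#' `bic_diff = BIC(M0) - BIC(M1)` with `BIC = -2 loglik + n_params * log(n)`;
#' `bic_diff > 0` declares a positive signal.
#'
#' M1 is fitted by EM (tolerance 1e-6 on the log-likelihood, up to 500
#' iterations) with `n_restarts` random initializations plus one deterministic
#' start at the null solution, which guarantees `ll_mix >= ll_null`.
#'
#' @param left_codes,right_codes integer code vectors from
#'   [encode_local_haplotypes]; chromosomes with `NA` on either side are
#'   dropped.
#' @param n_restarts random EM restarts (default 5).
#' @param max_iter,tol EM controls.
#' @param seed RNG seed for the random restarts.
#' @param alternative `"mixture"` (default) or `"saturated"`, the latter using
#'   the saturated joint multinomial as M1 (a cross-check variant, no EM).
#' @return list with `ll_null`, `ll_mix`, `bic_diff`, `n` (chromosomes used),
#'   `converged`.
#' @export
fit_block_models <- function(left_codes, right_codes, n_restarts = 5,
                             max_iter = 500, tol = 1e-6, seed = NULL,
                             alternative = c("mixture", "saturated")) {
  alternative <- match.arg(alternative)
  keep <- !is.na(left_codes) & !is.na(right_codes)
  l <- as.integer(factor(left_codes[keep]))
  r <- as.integer(factor(right_codes[keep]))
  n <- length(l)
  nl <- max(l, 0L)
  nr <- max(r, 0L)
  if (nl < 2L || nr < 2L)
    stop("need >= 2 distinct codes on each side (got ", nl, " left, ",
         nr, " right)")

  counts <- matrix(0, nl, nr)
  for (i in seq_len(n)) counts[l[i], r[i]] <- counts[l[i], r[i]] + 1
  rowm <- rowSums(counts) / n
  colm <- colSums(counts) / n

  safe_log <- function(x) log(pmax(x, .Machine$double.xmin))
  ll_null <- sum(counts * outer(safe_log(rowm), safe_log(colm), `+`))
  p_null <- (nl - 1) + (nr - 1)

  if (alternative == "saturated") {
    ll_mix <- sum(counts[counts > 0] * log(counts[counts > 0] / n))
    p_mix <- nl * nr - 1
    bic_diff <- (-2 * ll_null + p_null * log(n)) -
      (-2 * ll_mix + p_mix * log(n))
    return(list(ll_null = ll_null, ll_mix = ll_mix, bic_diff = bic_diff,
                n = n, converged = TRUE))
  }

  eps <- 1e-300
  em_once <- function(resp) {
    ll_old <- -Inf
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      # M step (responsibilities resp are for component 1, per cell)
      cr <- counts * resp
      cn <- counts - cr
      s1 <- sum(cr)
      w1 <- min(max(s1 / n, 1e-12), 1 - 1e-12)
      a1 <- .rowSums(cr, nl, nr) / s1
      b1 <- .colSums(cr, nl, nr) / s1
      a2 <- .rowSums(cn, nl, nr) / (n - s1)
      b2 <- .colSums(cn, nl, nr) / (n - s1)
      # E step
      c1 <- w1 * tcrossprod(a1, b1)
      tot <- c1 + (1 - w1) * tcrossprod(a2, b2) + eps
      resp <- c1 / tot
      ll <- sum(counts * log(tot))
      if (is.finite(ll) && abs(ll - ll_old) < tol) {
        converged <- TRUE
        ll_old <- ll
        break
      }
      ll_old <- ll
    }
    list(ll = ll_old, converged = converged)
  }

  with_seed(seed, {
    best <- em_once(matrix(0.5, nl, nr))   # null-start: guarantees ll >= ll_null
    for (s in seq_len(n_restarts)) {
      g <- matrix(stats::runif(nl * nr), nl, nr)
      fit <- em_once(g)
      if (fit$ll > best$ll) best <- fit
    }
    p_mix <- 1 + 2 * (nl - 1) + 2 * (nr - 1)
    bic_diff <- (-2 * ll_null + p_null * log(n)) -
      (-2 * best$ll + p_mix * log(n))
    list(ll_null = ll_null, ll_mix = best$ll, bic_diff = bic_diff,
         n = n, converged = best$converged)
  })
}

#' Scan a region for extended-haplotype segments
#'
#' Slides windows of each requested size across the region. For the window
#' `[b1, b2]` the left code block is the first `k` SNPs right of `b1` and the
#' right code block the last `k` SNPs left of `b2`; a positive
#' `bic_diff` from [fit_block_models] indicates unusually high linkage between
#' the two distant points, the imprint of a segment transmitted as a unit.
#' Windows where either side has fewer than 2 distinct codes are skipped
#' (`bic_diff = NA`).
#'
#' @param gm a [genotype_matrix] (one chromosome).
#' @param window_sizes_bp vector of window sizes in bp; the published analyses
#'   of this kind use about 7 sizes spanning 0.4--1 Mb.
#' @param step_bp step between window starts; default half the smallest
#'   window.
#' @param k SNPs per code block (default 2).
#' @param seed RNG seed (EM restarts are sub-seeded per window).
#' @return object of class `scan_result`: list with `windows` (data.frame
#'   `left_bp`, `right_bp`, `window_size`, `bic_diff`, `n_chromosomes`) and
#'   `segments` (merged positive windows, see [merge_positive_windows]).
#' @export
scan_region <- function(gm, window_sizes_bp, step_bp = NULL, k = 2,
                        seed = NULL) {
  if (length(window_sizes_bp) == 0L) stop("window_sizes_bp must be non-empty")
  pos <- gm$variants$pos
  span <- max(pos) - min(pos)
  if (any(window_sizes_bp > span))
    stop("window size ", max(window_sizes_bp), " exceeds region span ", span)
  if (is.null(step_bp)) step_bp <- floor(min(window_sizes_bp) / 2)

  rows <- list()
  widx <- 0L
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  for (w in sort(window_sizes_bp)) {
    starts <- seq(min(pos), max(pos) - w, by = step_bp)
    for (b1 in starts) {
      b2 <- b1 + w
      widx <- widx + 1L
      lc <- tryCatch(encode_local_haplotypes(gm, b1, "right", k),
                     error = function(e) NULL)
      rc <- tryCatch(encode_local_haplotypes(gm, b2, "left", k),
                     error = function(e) NULL)
      fit <- NULL
      if (!is.null(lc) && !is.null(rc)) {
        sub_seed <- if (is.null(base_seed)) NULL else
          (base_seed + widx) %% .Machine$integer.max
        fit <- tryCatch(
          fit_block_models(lc, rc, seed = sub_seed),
          error = function(e) NULL)
      }
      rows[[widx]] <- data.frame(
        left_bp = b1, right_bp = b2, window_size = w,
        bic_diff = if (is.null(fit)) NA_real_ else fit$bic_diff,
        n_chromosomes = if (is.null(fit)) NA_integer_ else fit$n)
    }
  }
  windows <- do.call(rbind, rows)
  res <- structure(list(windows = windows, segments = NULL),
                   class = "scan_result")
  res$segments <- merge_positive_windows(res)
  res
}

#' Merge overlapping positive scan windows into candidate segments
#'
#' @param scan a `scan_result` (or its `windows` data.frame).
#' @return data.frame `start_bp`, `end_bp`, `max_bic_diff`, `n_windows`
#'   (zero rows if no window is positive).
#' @export
merge_positive_windows <- function(scan) {
  windows <- if (inherits(scan, "scan_result")) scan$windows else scan
  pos <- windows[!is.na(windows$bic_diff) & windows$bic_diff > 0, , drop = FALSE]
  empty <- data.frame(start_bp = numeric(0), end_bp = numeric(0),
                      max_bic_diff = numeric(0), n_windows = integer(0))
  if (nrow(pos) == 0L) return(empty)
  pos <- pos[order(pos$left_bp, pos$right_bp), , drop = FALSE]
  segs <- list()
  cur <- list(start = pos$left_bp[1], end = pos$right_bp[1],
              max_bic = pos$bic_diff[1], n = 1L)
  if (nrow(pos) > 1L) for (i in 2:nrow(pos)) {
    if (pos$left_bp[i] <= cur$end) {
      cur$end <- max(cur$end, pos$right_bp[i])
      cur$max_bic <- max(cur$max_bic, pos$bic_diff[i])
      cur$n <- cur$n + 1L
    } else {
      segs[[length(segs) + 1L]] <- cur
      cur <- list(start = pos$left_bp[i], end = pos$right_bp[i],
                  max_bic = pos$bic_diff[i], n = 1L)
    }
  }
  segs[[length(segs) + 1L]] <- cur
  data.frame(start_bp = vapply(segs, `[[`, numeric(1), "start"),
             end_bp = vapply(segs, `[[`, numeric(1), "end"),
             max_bic_diff = vapply(segs, `[[`, numeric(1), "max_bic"),
             n_windows = vapply(segs, `[[`, integer(1), "n"))
}

#' @export
print.scan_result <- function(x, ...) {
  npos <- sum(!is.na(x$windows$bic_diff) & x$windows$bic_diff > 0)
  cat("scan_result:", nrow(x$windows), "windows,", npos, "positive,",
      nrow(x$segments), "merged segment(s)\n")
  if (nrow(x$segments)) print(x$segments)
  invisible(x)
}
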