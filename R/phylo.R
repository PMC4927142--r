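#' Pairwise Hamming distance matrix of haplotype sequences
#'
#' Counts differing sites between every pair of equal-length allele vectors;
#' positions missing in either member of a pair are dropped pairwise.
#'
#' @param haps matrix of 0/1/`NA` alleles (one sequence per row, rownames used
#'   as labels), or a character vector of equal-length allele strings.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
hamming_matrix <- function(haps) {
  if (is.character(haps)) {
    lens <- nchar(haps)
    if (length(unique(lens)) != 1L) stop("sequences differ in length")
    haps <- do.call(rbind, lapply(strsplit(haps, ""), function(x)
      suppressWarnings(as.integer(x))))
  }
  haps <- as.matrix(haps)
  n <- nrow(haps)
  labs <- rownames(haps)
  if (is.null(labs)) labs <- paste0("seq", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  if (!anyNA(haps)) {
    x <- haps
    D <- x %*% t(1 - x) + (1 - x) %*% t(x)
    dimnames(D) <- list(labs, labs)
  } else {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ok <- !is.na(haps[i, ]) & !is.na(haps[j, ])
      D[i, j] <- D[j, i] <- sum(haps[i, ok] != haps[j, ok])
    }
  }
  D
}

#' Majority-consensus haplotypes per group
#'
#' @param haps allele matrix (rows = chromosomes).
#' @param groups grouping vector (one label per row).
#' @return matrix of consensus 0/1 sequences, one row per group (ties at a
#'   site resolve to 1).
#' @export
consensus_haplotypes <- function(haps, groups) {
  stopifnot(nrow(haps) == length(groups))
  gs <- sort(unique(groups))
  out <- t(vapply(gs, function(g) {
    m <- colMeans(haps[groups == g, , drop = FALSE], na.rm = TRUE)
    as.integer(m >= 0.5)
  }, integer(ncol(haps))))
  rownames(out) <- as.character(gs)
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining. Ties in the Q-matrix are broken by the lowest
#' index pair (row-major); negative branch lengths are clamped to zero with
#' the deficit moved to the sister branch, preserving the path length between
#' the joined pair. Returns an unrooted tree in Newick format.
#'
#' @param D symmetric distance matrix with labels (>= 2 taxa).
#' @return Newick string (unrooted; trifurcating root for >= 3 taxa).
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 2L) stop("need >= 2 taxa")
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))

  fmt <- function(x) format(x, digits = 10, scientific = FALSE, trim = TRUE)
  clamp_pair <- function(li, lj, dij) {
    if (li < 0) { li <- 0; lj <- dij }
    if (lj < 0) { lj <- 0; li <- dij }
    c(li, lj)
  }

  if (n == 2L) {
    h <- D[1, 2] / 2
    return(paste0("(", labs[1], ":", fmt(h), ",", labs[2], ":", fmt(h), ");"))
  }

  nodes <- labs
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # lowest index pair on ties, row-major
    best <- c(1L, 2L); bq <- Q[1, 2]
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (Q[i, j] < bq - 1e-12) { bq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    l <- clamp_pair(li, lj, D[i, j])
    new_node <- paste0("(", nodes[i], ":", fmt(l[1]), ",",
                       nodes[j], ":", fmt(l[2]), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dk <- dk[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, dk), c(dk, 0))
    nodes <- c(nodes[-c(i, j)], new_node)
  }

  # final three nodes: closed-form star lengths
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- max((d12 + d13 - d23) / 2, 0)
  l2 <- max((d12 + d23 - d13) / 2, 0)
  l3 <- max((d13 + d23 - d12) / 2, 0)
  paste0("(", nodes[1], ":", fmt(l1), ",", nodes[2], ":", fmt(l2), ",",
         nodes[3], ":", fmt(l3), ");")
}

#' Write a Newick tree to file
#' @param newick Newick string.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(newick, path) {
  writeLines(newick, path)
  invisible(path)
}

#' Assign an outgroup sequence to its nearest clade
#'
#' @param outgroup_sequence 0/1 allele vector.
#' @param clade_consensus matrix of clade consensus sequences (rows = clades,
#'   rownames = clade ids), aligned with the outgroup.
#' @return list `clade` (row label of the minimum-Hamming clade, `NA` if all
#'   distances tie), `distances` (named vector), `ambiguous` (TRUE if the
#'   minimum is tied).
#' @export
assign_outgroup <- function(outgroup_sequence, clade_consensus) {
  clade_consensus <- as.matrix(clade_consensus)
  if (length(outgroup_sequence) != ncol(clade_consensus))
    stop("outgroup and consensus sequences differ in length")
  d <- apply(clade_consensus, 1L, function(s) {
    ok <- !is.na(s) & !is.na(outgroup_sequence)
    sum(s[ok] != outgroup_sequence[ok])
  })
  mins <- which(d == min(d))
  if (length(mins) > 1L)
    return(list(clade = NA_character_, distances = d, ambiguous = TRUE))
  list(clade = names(d)[mins], distances = d, ambiguous = FALSE)
}
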