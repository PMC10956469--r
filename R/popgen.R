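#' Mean observed and expected heterozygosity
#'
#' Genotypes are coded 0/1/2 as the count of the alternate allele, `NA` for
#' missing. Per locus, `Ho` is the fraction of heterozygotes among called
#' genotypes and `He` the unbiased expected heterozygosity
#' `2*p*q * 2N/(2N - 1)` (N = called genotypes); both are averaged over loci
#' with at least two called genotypes.
#'
#' @param geno integer matrix, samples x loci, values 0/1/2 or `NA`.
#' @return list with `Ho`, `He` (means over loci) and a per-locus tibble.
#' @export
heterozygosity <- function(geno) {
  stopifnot(is.matrix(geno))
  n_called <- colSums(!is.na(geno))
  keep <- n_called >= 2
  if (!any(keep)) stop("no locus with >= 2 called genotypes")
  g <- geno[, keep, drop = FALSE]
  nc <- n_called[keep]
  ho <- colSums(g == 1, na.rm = TRUE) / nc
  p <- colSums(g, na.rm = TRUE) / (2 * nc)
  he <- 2 * p * (1 - p) * (2 * nc) / (2 * nc - 1)
  per_locus <- tibble::tibble(
    locus = colnames(g) %||% as.character(seq_len(ncol(g))),
    n_called = nc, p_alt = p, Ho = ho, He = he
  )
  list(Ho = mean(ho), He = mean(he), per_locus = per_locus)
}

#' Pairwise Weir-Cockerham F_ST between two populations
#'
#' Computes the Weir & Cockerham (1984) theta-hat for biallelic loci from the
#' a/b/c variance components, with the multilocus estimate formed as the
#' ratio of summed components. Loci monomorphic across both populations (or
#' with fewer than two called genotypes in either) are excluded.
#'
#' @param geno_a,geno_b integer genotype matrices (samples x loci, 0/1/2/NA)
#'   on the same locus panel.
#' @return list with `theta` (multilocus), and a per-locus tibble of
#'   components `a`, `b`, `c` and per-locus theta.
#' @export
pairwise_fst <- function(geno_a, geno_b) {
  stopifnot(ncol(geno_a) == ncol(geno_b))
  n1 <- colSums(!is.na(geno_a))
  n2 <- colSums(!is.na(geno_b))
  p1 <- colSums(geno_a, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(geno_b, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(geno_a == 1, na.rm = TRUE) / n1
  h2 <- colSums(geno_b == 1, na.rm = TRUE) / n2
  poly <- n1 >= 2 & n2 >= 2 &
    !(pmin(p1, p2) == 0 & pmax(p1, p2) == 0) &
    !(pmin(p1, p2) == 1 & pmax(p1, p2) == 1)
  if (!any(poly)) stop("no polymorphic locus shared by the two populations")

  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2

  a <- a[poly]; b <- b[poly]; cc <- cc[poly]
  per_locus <- tibble::tibble(
    locus = (colnames(geno_a) %||% as.character(seq_len(ncol(geno_a))))[poly],
    a = a, b = b, c = cc, theta = a / (a + b + cc)
  )
  list(theta = sum(a) / sum(a + b + cc), per_locus = per_locus)
}

#' Principal component analysis of a genotype matrix
#'
#' Genotypes coded 0/1/2 are mean-imputed at missing entries, columns are
#' mean-centered, and scores are taken from the singular value decomposition.
#' Component signs are fixed by making each component's largest-magnitude
#' locus loading positive, so results are deterministic.
#'
#' @param geno integer genotype matrix (samples x loci, 0/1/2/NA).
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `loadings`, `sdev`.
#' @export
pca_genotypes <- function(geno, n_components = min(dim(geno), 10L)) {
  stopifnot(is.matrix(geno), nrow(geno) >= 2)
  x <- apply(geno, 2, function(col) {
    m <- mean(col, na.rm = TRUE)
    if (is.nan(m)) m <- 0
    col[is.na(col)] <- m
    col - m
  })
  x <- matrix(x, nrow = nrow(geno), dimnames = dimnames(geno))
  k <- min(n_components, nrow(x) - 1L, ncol(x))
  if (all(abs(x) < 1e-12)) {
    return(list(scores = matrix(0, nrow(x), k,
                                dimnames = list(rownames(geno), paste0("PC", seq_len(k)))),
                loadings = matrix(0, ncol(x), k), sdev = rep(0, k)))
  }
  sv <- svd(x, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(k)], k), 2, flip, `*`)
  dimnames(scores) <- list(rownames(geno), paste0("PC", seq_len(k)))
  list(scores = scores,
       loadings = sweep(sv$v, 2, flip, `*`),
       sdev = sv$d[seq_len(k)] / sqrt(nrow(x) - 1))
}

#' Seeded random subsample of samples per group
#'
#' Utility for replicated F_ST / PCA summaries on a fixed-size random subset
#' of broodstock per program.
#'
#' @param ids sample identifiers.
#' @param groups grouping factor aligned with `ids` (e.g. program).
#' @param n_per_group subset size; groups smaller than this are kept whole.
#' @param seed integer seed.
#' @return character vector of selected ids.
#' @export
subsample_broodstock <- function(ids, groups, n_per_group = 300L, seed = 1L) {
  stopifnot(length(ids) == length(groups))
  set.seed(seed)
  unlist(lapply(split(as.character(ids), groups), function(g) {
    if (length(g) <= n_per_group) g else sample(g, n_per_group)
  }), use.names = FALSE)
}
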