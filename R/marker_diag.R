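#' Per-marker Mendelian-incompatibility rates over assigned trios
#'
#' For every locus, counts the trios (among the supplied pedigree) in which
#' all three members are called and the observed genotypes admit no
#' Mendelian-consistent transmission, and flags loci whose incompatibility
#' rate exceeds `exclude_rate` for removal from the analysis panel.
#'
#' @param pedigree tibble with `offspring_fish`, `mother_fish`,
#'   `father_fish`.
#' @param geno fish-level genotype matrix.
#' @param exclude_rate exclusion threshold on the incompatibility rate.
#' @return tibble with `locus`, `n_trios_called`, `n_incompatible`,
#'   `incompatibility_rate`, `excluded`.
#' @export
per_marker_incompatibility_rate <- function(pedigree, geno, exclude_rate = 0.02) {
  L <- ncol(geno)
  M <- mendel_array()
  incompat27 <- vapply(0:26, function(i) {
    om <- i %% 3; of <- (i %/% 3) %% 3; oo <- i %/% 9
    M[om + 1, of + 1, oo + 1] == 0
  }, logical(1))
  Gm <- geno[pedigree$mother_fish, , drop = FALSE]
  Gf <- geno[pedigree$father_fish, , drop = FALSE]
  Go <- geno[pedigree$offspring_fish, , drop = FALSE]
  idx <- 1L + Gm + 3L * Gf + 9L * Go
  called <- !is.na(idx)
  inc <- matrix(incompat27[idx], nrow(idx), L)
  n_called <- unname(colSums(called))
  n_inc <- unname(colSums(inc, na.rm = TRUE))
  rate <- ifelse(n_called > 0, n_inc / n_called, NA_real_)
  tibble::tibble(
    locus = colnames(geno) %||% as.character(seq_len(L)),
    n_trios_called = n_called, n_incompatible = n_inc,
    incompatibility_rate = rate,
    excluded = !is.na(rate) & rate > exclude_rate
  )
}

#' Probability that a true trio presents as Mendelian-incompatible
#'
#' Exhaustive enumeration for one biallelic locus: parents drawn from
#' Hardy-Weinberg proportions at frequency `p`, offspring by Mendelian
#' transmission, each of the six gene copies observed with independent
#' per-copy error `epsilon`; returns the probability that the observed trio
#' admits no error-free Mendelian transmission. `Q(0) = 0` and `Q` is
#' increasing in `epsilon` near 0 for polymorphic `p`.
#'
#' @param epsilon per-gene-copy error rate.
#' @param p alternate-allele frequency.
#' @return scalar probability.
#' @export
trio_incompatibility_prob <- function(epsilon, p) {
  K <- genotype_error_kernel(epsilon)
  M <- mendel_array()
  h <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  q <- 0
  for (tm in 1:3) for (tf in 1:3) for (to in 1:3) {
    pr_true <- h[tm] * h[tf] * M[tm, tf, to]
    if (pr_true == 0) next
    for (om in 1:3) for (of in 1:3) for (oo in 1:3) {
      if (M[om, of, oo] == 0)
        q <- q + pr_true * K[tm, om] * K[tf, of] * K[to, oo]
    }
  }
  q
}

#' Minimum per-gene-copy error rate explaining observed incompatibilities
#'
#' Inverts [trio_incompatibility_prob()] by bisection: finds the error rate
#' at which a true trio would present the observed per-locus Mendelian
#' incompatibility rate. An observed rate of 0 gives 0; rates above the
#' attainable maximum are capped at `eps_max` with a warning.
#'
#' @param observed_rate per-locus incompatibility rate.
#' @param p locus alternate-allele frequency.
#' @param eps_max upper bracket of the search.
#' @param tol bisection tolerance on epsilon.
#' @return estimated minimum error rate `epsilon_hat`.
#' @export
estimate_min_error_rate <- function(observed_rate, p, eps_max = 0.499,
                                    tol = 1e-7) {
  stopifnot(observed_rate >= 0, observed_rate <= 1)
  if (observed_rate == 0) return(0)
  if (trio_incompatibility_prob(eps_max, p) < observed_rate) {
    warning("observed incompatibility rate exceeds the attainable maximum; capped")
    return(eps_max)
  }
  lo <- 0; hi <- eps_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (trio_incompatibility_prob(mid, p) < observed_rate) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Full per-marker diagnostics with error-rate estimates
#'
#' @param pedigree accepted trios.
#' @param geno fish-level genotype matrix.
#' @param freqs per-locus allele frequencies aligned with `geno` columns.
#' @param exclude_rate exclusion threshold.
#' @return the [per_marker_incompatibility_rate()] table with `epsilon_hat`.
#' @export
marker_diagnostics <- function(pedigree, geno, freqs, exclude_rate = 0.02) {
  d <- per_marker_incompatibility_rate(pedigree, geno, exclude_rate)
  d$epsilon_hat <- vapply(seq_len(nrow(d)), function(i) {
    if (is.na(d$incompatibility_rate[i]) || is.na(freqs[i]) ||
        freqs[i] <= 0 || freqs[i] >= 1) return(NA_real_)
    estimate_min_error_rate(d$incompatibility_rate[i], freqs[i])
  }, numeric(1))
  d
}
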