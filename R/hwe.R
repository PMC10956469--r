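#' Exact test of Hardy-Weinberg equilibrium for a biallelic locus
#'
#' Computes the heterozygote-excess statistic D and an exact two-sided
#' p-value from the conditional (Levene-Haldane) distribution of the
#' heterozygote count given the allele counts.
#'
#' D is half the deviation of the observed heterozygote count from its
#' Hardy-Weinberg expectation, `D = (n_AB - 2*p*q*N) / 2`, with allele
#' frequencies taken from the allele counts. The p-value sums the conditional
#' probabilities `P(h)` of every admissible heterozygote count `h` (same
#' parity as the minor-allele count) whose probability does not exceed that
#' of the observed count (the "selome" convention). When the locus is
#' monomorphic, `D = 0` and `p = 1`.
#'
#' @param n_AA,n_AB,n_BB non-negative genotype counts.
#' @return a list with fields `n_AA`, `n_AB`, `n_BB`, `D`, `p_value`.
#' @examples
#' hwe_exact(1186, 709, 70)
#' @export
hwe_exact <- function(n_AA, n_AB, n_BB) {
  stopifnot(length(n_AA) == 1, length(n_AB) == 1, length(n_BB) == 1,
            n_AA >= 0, n_AB >= 0, n_BB >= 0)
  n <- as.integer(n_AA + n_AB + n_BB)
  if (n < 1) stop("at least one genotype required")
  nB <- as.integer(n_AB + 2L * n_BB)
  nA <- as.integer(2L * n) - nB
  p <- nB / (2 * n)
  D <- (n_AB - 2 * p * (1 - p) * n) / 2

  if (nA == 0L || nB == 0L) {
    return(list(n_AA = n_AA, n_AB = n_AB, n_BB = n_BB, D = 0, p_value = 1))
  }

  minor <- min(nA, nB)
  h <- seq.int(minor %% 2L, minor, by = 2L)
  logp <- hwe_log_cond_prob(h, nA, nB, n)
  logp <- logp - max(logp)
  prob <- exp(logp)
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_AB, h)]
  pval <- sum(prob[prob <= p_obs * (1 + 1e-12)])
  list(n_AA = n_AA, n_AB = n_AB, n_BB = n_BB, D = D, p_value = min(pval, 1))
}

# log of the unnormalized Levene-Haldane conditional probability of h
# heterozygotes given allele counts nA, nB in N diploids:
#   P(h) propto 2^h * N! / ( ((nA-h)/2)! * h! * ((nB-h)/2)! )
hwe_log_cond_prob <- function(h, nA, nB, n) {
  h * log(2) + lgamma(n + 1) -
    lgamma((nA - h) / 2 + 1) - lgamma(h + 1) - lgamma((nB - h) / 2 + 1)
}
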