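#' Genotyping-error kernel for a biallelic locus
#'
#' Each of the two gene copies is observed correctly with probability
#' `1 - epsilon` and flipped to the other allele with probability `epsilon`,
#' independently. Returns the 3x3 matrix of emission probabilities of the
#' unordered observed genotype (rows: true genotype 0/1/2 alternate-allele
#' copies; columns: observed genotype). Rows sum to 1.
#'
#' @param epsilon per-gene-copy error rate in `[0, 0.5)`.
#' @return 3x3 numeric matrix `K[true + 1, observed + 1]`.
#' @export
genotype_error_kernel <- function(epsilon) {
  stopifnot(epsilon >= 0, epsilon < 0.5)
  e <- epsilon
  matrix(c(
    (1 - e)^2,     2 * e * (1 - e),     e^2,
    e * (1 - e),   (1 - e)^2 + e^2,     e * (1 - e),
    e^2,           2 * e * (1 - e),     (1 - e)^2
  ), nrow = 3, byrow = TRUE,
  dimnames = list(true = 0:2, observed = 0:2))
}

# Mendelian transmission array M[gm+1, gf+1, go+1]: each parent transmits the
# alternate allele with probability g/2.
mendel_array <- function() {
  M <- array(0, dim = c(3, 3, 3))
  for (gm in 0:2) for (gf in 0:2) {
    pm <- gm / 2; pf <- gf / 2
    M[gm + 1, gf + 1, 1] <- (1 - pm) * (1 - pf)
    M[gm + 1, gf + 1, 2] <- pm * (1 - pf) + (1 - pm) * pf
    M[gm + 1, gf + 1, 3] <- pm * pf
  }
  M
}

# Index of an observed trio (gm, gf, go) into the 27-entry likelihood tables.
trio_index <- function(gm, gf, go) 1L + gm + 3L * gf + 9L * go

#' Precompute per-locus trio-likelihood tables
#'
#' Builds, for every locus, the likelihood of each observed (mother, father,
#' offspring) genotype configuration under two hypotheses: parental (parents
#' drawn from Hardy-Weinberg proportions at the supplied frequencies,
#' offspring by Mendelian transmission, all three observations passed through
#' the per-gene-copy error kernel) and unrelated (all three drawn
#' independently from HWE). Also builds the analogous single parent-offspring
#' tables used for candidate screening and the mother-only/father-only
#' hypotheses, and the Mendelian-incompatibility indicator of each observed
#' configuration (ignoring error).
#'
#' Loci that are monomorphic at the supplied frequencies are flagged and
#' contribute zero to every LOD.
#'
#' @param freqs numeric vector of alternate-allele frequencies per locus.
#' @param epsilon per-gene-copy genotyping error rate.
#' @return an object of class `trio_tables`.
#' @export
trio_tables <- function(freqs, epsilon = 0.005) {
  stopifnot(all(freqs >= 0 & freqs <= 1), epsilon > 0, epsilon < 0.5)
  L <- length(freqs)
  K <- genotype_error_kernel(epsilon)
  M <- mendel_array()
  p <- freqs
  h <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)        # L x 3 HWE priors
  m <- h %*% K                                        # L x 3 observed marginals

  # T[tm, tf, oo] = sum_to M[tm, tf, to] * K[to, oo]
  Tarr <- array(0, dim = c(3, 3, 3))
  for (oo in 1:3) Tarr[, , oo] <- apply(M, c(1, 2), function(v) sum(v * K[, oo]))

  # parental trio likelihood: Lp = A %*% W with A[l, (tm,tf)] = h_tm * h_tf
  A <- matrix(0, L, 9)
  W <- matrix(0, 9, 27)
  for (tm in 1:3) for (tf in 1:3) {
    j <- tm + 3 * (tf - 1)
    A[, j] <- h[, tm] * h[, tf]
    w <- array(0, dim = c(3, 3, 3))
    for (om in 1:3) for (of in 1:3) for (oo in 1:3)
      w[om, of, oo] <- K[tm, om] * K[tf, of] * Tarr[tm, tf, oo]
    W[j, ] <- as.vector(w)
  }
  Lp <- A %*% W                                       # L x 27, idx = trio_index
  Lu <- matrix(0, L, 27)
  for (om in 0:2) for (of in 0:2) for (oo in 0:2)
    Lu[, trio_index(om, of, oo)] <- m[, om + 1] * m[, of + 1] * m[, oo + 1]

  # single parent-offspring tables, other parent integrated over HWE:
  # Tr[l, tp, to] = sum_ta h[l, ta] * M[tp, ta, to]
  B <- matrix(0, L, 9)
  V <- matrix(0, 9, 9)
  for (tp in 1:3) for (to in 1:3) {
    j <- tp + 3 * (to - 1)
    Tr <- h %*% M[tp, , ]                              # L x 3 over to
    B[, j] <- h[, tp] * Tr[, to]
    v <- outer(K[tp, ], K[to, ])                       # op x oo
    V[j, ] <- as.vector(v)
  }
  Ppo <- B %*% V                                      # L x 9, idx = 1+op+3*oo
  Upo <- matrix(0, L, 9)
  for (op in 0:2) for (oo in 0:2)
    Upo[, 1 + op + 3 * oo] <- m[, op + 1] * m[, oo + 1]

  mono <- p <= 0 | p >= 1
  lr_trio <- log10(Lp / Lu)
  lr_po <- log10(Ppo / Upo)
  lr_trio[mono, ] <- 0
  lr_po[mono, ] <- 0

  incompat27 <- vapply(0:26, function(i) {
    om <- i %% 3; of <- (i %/% 3) %% 3; oo <- i %/% 9
    M[om + 1, of + 1, oo + 1] == 0
  }, logical(1))

  structure(list(freqs = freqs, epsilon = epsilon, n_loci = L,
                 lr_trio = lr_trio, lr_po = lr_po,
                 incompat27 = incompat27, monomorphic = mono,
                 kernel = K, mendel = M, marg = m),
            class = "trio_tables")
}

#' Trio log-likelihood ratio (LOD) with per-locus incompatibility flags
#'
#' Sums, over loci called in all three members (monomorphic loci excluded),
#' the log10 ratio of the parental to the unrelated likelihood from
#' [trio_tables()]. A locus is flagged incompatible when the observed trio
#' admits no Mendelian-consistent transmission if the observations are taken
#' at face value; incompatible loci still contribute their (strongly
#' negative) likelihood terms to the LOD.
#'
#' @param go,gm,gf integer genotype vectors (0/1/2/NA) for offspring, mother,
#'   father on the table's locus panel.
#' @param tables a [trio_tables()] object.
#' @param min_loci minimum number of co-called informative loci; fewer
#'   returns `NULL` (the pair is not evaluable for this offspring).
#' @return list with `lod`, `n_loci`, `n_compatible`, `n_incompatible`, and
#'   the logical `incompatible` flags over the used loci, or `NULL`.
#' @export
trio_lod <- function(go, gm, gf, tables, min_loci = 50L) {
  L <- tables$n_loci
  stopifnot(length(go) == L, length(gm) == L, length(gf) == L)
  use <- which(!is.na(go) & !is.na(gm) & !is.na(gf) & !tables$monomorphic)
  if (length(use) < min_loci) return(NULL)
  idx <- trio_index(gm[use], gf[use], go[use])
  lod <- sum(tables$lr_trio[cbind(use, idx)])
  inc <- tables$incompat27[idx]
  list(lod = lod, n_loci = length(use),
       n_compatible = sum(!inc), n_incompatible = sum(inc),
       incompatible = stats::setNames(inc, use))
}

# Single parent-offspring LOD (other parent integrated out), same conventions.
parent_offspring_lod <- function(go, gp, tables) {
  use <- which(!is.na(go) & !is.na(gp) & !tables$monomorphic)
  idx <- 1L + gp[use] + 3L * go[use]
  sum(tables$lr_po[cbind(use, idx)])
}

# Offspring-side weight matrix for the single-parent LOD prescreen.
# Returns n_off x 3L matrix Wo with Wo[o, 3*(l-1) + gp + 1] equal to the
# parent-offspring log10 LR at locus l given parent genotype gp and the
# offspring's observed genotype (0 when the offspring is missing at l), so
# that Wo %*% t(onehot(adults)) is the exact single-parent LOD matrix.
po_weight_matrix <- function(geno_off, tables) {
  L <- tables$n_loci
  n <- nrow(geno_off)
  W <- matrix(0, n, 3L * L)
  lmat <- matrix(rep(seq_len(L), each = n), n, L)
  for (gp in 0:2) {
    idx <- 1L + gp + 3L * geno_off                     # n x L, NA where missing
    flat <- lmat + (idx - 1L) * L
    v <- tables$lr_po[flat]
    v[is.na(v)] <- 0
    W[, 3L * (seq_len(L) - 1L) + gp + 1L] <- matrix(v, n, L)
  }
  W
}

# One-hot encoding of called genotypes: n x 3L indicator matrix.
genotype_onehot <- function(geno) {
  L <- ncol(geno)
  n <- nrow(geno)
  A <- matrix(0, n, 3L * L)
  for (g in 0:2) {
    ind <- !is.na(geno) & geno == g
    A[, 3L * (seq_len(L) - 1L) + g + 1L] <- ind + 0
  }
  A
}
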