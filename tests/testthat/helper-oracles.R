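# Independent oracles used to validate the package implementations.
# Each is written as a direct, unoptimized transcription of the underlying
# definition, sharing no code with the package internals it checks.

# exhaustive-enumeration trio LOD for one biallelic locus
oracle_locus_lod <- function(go, gm, gf, p, eps) {
  K <- matrix(c((1 - eps)^2, 2 * eps * (1 - eps), eps^2,
                eps * (1 - eps), (1 - eps)^2 + eps^2, eps * (1 - eps),
                eps^2, 2 * eps * (1 - eps), (1 - eps)^2),
              3, 3, byrow = TRUE)
  h <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  mendel <- function(tm, tf, to) {
    pm <- tm / 2; pf <- tf / 2
    c((1 - pm) * (1 - pf), pm * (1 - pf) + (1 - pm) * pf, pm * pf)[to + 1]
  }
  Lp <- 0; Lu <- 0
  for (tm in 0:2) for (tf in 0:2) for (to in 0:2) {
    w <- K[tm + 1, gm + 1] * K[tf + 1, gf + 1] * K[to + 1, go + 1]
    Lp <- Lp + h[tm + 1] * h[tf + 1] * mendel(tm, tf, to) * w
    Lu <- Lu + h[tm + 1] * h[tf + 1] * h[to + 1] * w
  }
  log10(Lp / Lu)
}

oracle_trio_lod <- function(go, gm, gf, p, eps) {
  tot <- 0
  for (l in seq_along(p)) {
    if (is.na(go[l]) || is.na(gm[l]) || is.na(gf[l])) next
    tot <- tot + oracle_locus_lod(go[l], gm[l], gf[l], p[l], eps)
  }
  tot
}

# brute-force Levene-Haldane exact HWE p-value: enumerate every admissible
# heterozygote count and sum exact conditional probabilities computed from
# factorials on the log scale via cumulative sums
oracle_hwe_p <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nB <- nAB + 2 * nBB
  nA <- 2 * n - nB
  if (nA == 0 || nB == 0) return(1)
  lf <- c(0, cumsum(log(seq_len(2 * n))))     # lf[k+1] = log(k!)
  lfac <- function(k) lf[k + 1]
  minor <- min(nA, nB)
  hs <- seq(minor %% 2, minor, by = 2)
  logp <- vapply(hs, function(h) {
    h * log(2) + lfac(n) - lfac((nA - h) / 2) - lfac(h) - lfac((nB - h) / 2)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  pobs <- pr[which(hs == nAB)]
  sum(pr[pr <= pobs * (1 + 1e-12)])
}

# independent transcription of the Weir & Cockerham (1984) theta-hat for two
# populations at one biallelic locus, written scalar-by-scalar
oracle_wc_components <- function(ga, gb) {
  ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
  n1 <- length(ga); n2 <- length(gb)
  p1 <- sum(ga) / (2 * n1); p2 <- sum(gb) / (2 * n2)
  h1 <- mean(ga == 1); h2 <- mean(gb == 1)
  r <- 2
  nbar <- mean(c(n1, n2))
  CV2 <- ((n1 - nbar)^2 + (n2 - nbar)^2) / (r * nbar^2) * r / (r - 1)
  nc <- nbar * (1 - CV2 * (r - 1) / r)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
    (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

oracle_wc_theta <- function(geno_a, geno_b) {
  comps <- sapply(seq_len(ncol(geno_a)), function(l)
    oracle_wc_components(geno_a[, l], geno_b[, l]))
  poly <- sapply(seq_len(ncol(geno_a)), function(l) {
    g <- c(geno_a[, l], geno_b[, l])
    g <- g[!is.na(g)]
    pbar <- sum(g) / (2 * length(g))
    pbar > 0 && pbar < 1
  })
  sum(comps["a", poly]) / sum(colSums(comps)[poly])
}
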