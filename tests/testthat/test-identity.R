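test_that("match fraction uses co-called loci and the shared-locus floor", {
  g1 <- rep(1L, 90)
  g2 <- g1
  expect_equal(match_fraction(g1, g2, 60)$match_fraction, 1)
  # 92 co-called loci with 5 mismatches: 87/92 < 0.95
  a <- rep(0L, 92); b <- a; b[1:5] <- 2L
  mf <- match_fraction(a, b, 60)
  expect_equal(mf$match_fraction, 87 / 92)
  expect_lt(mf$match_fraction, 0.95)
  # fewer than min shared loci: no edge
  c1 <- c(rep(0L, 40), rep(NA, 52)); c2 <- rep(0L, 92)
  expect_null(match_fraction(c1, c2, 60))
  # missing in either sample excluded from the denominator
  d1 <- c(NA, rep(1L, 70)); d2 <- c(2L, rep(1L, 70))
  expect_equal(match_fraction(d1, d2, 60)$shared_loci, 70L)
  expect_equal(match_fraction(d1, d2, 60)$match_fraction, 1)
})

test_that("edge matrix agrees with pairwise match_fraction", {
  set.seed(8)
  g <- matrix(sample(c(0:2, NA), 8 * 80, TRUE, prob = c(.3, .3, .3, .1)), 8, 80)
  g[2, ] <- g[1, ]; g[2, 3] <- NA          # near-duplicate pair
  rownames(g) <- sprintf("s%02d", 1:8)
  ed <- identity_edges(g, threshold = 0.95, min_shared_loci = 60)
  expect_true(all(ed$match_fraction >= 0.95))
  for (k in seq_len(nrow(ed))) {
    mf <- match_fraction(g[ed$sample_a[k], ], g[ed$sample_b[k], ], 60)
    expect_equal(ed$match_fraction[k], mf$match_fraction)
    expect_equal(ed$shared_loci[k], mf$shared_loci)
  }
  expect_true(any(ed$sample_a == "s01" & ed$sample_b == "s02"))
})

test_that("components merge transitively and singletons remain alone", {
  g <- matrix(1L, 4, 80, dimnames = list(c("A", "B", "C", "D"), NULL))
  g[4, 1:40] <- 0L                          # D differs
  edges <- tibble::tibble(sample_a = c("A", "B"), sample_b = c("B", "C"),
                          shared_loci = 80L, matching_loci = 80L,
                          match_fraction = 1)
  cl <- build_clusters(g, edges)
  expect_equal(sort(cl$n_members, decreasing = TRUE), c(3L, 1L))
  three <- cl$members[[which(cl$n_members == 3)]]
  expect_setequal(three, c("A", "B", "C"))
  # no edges: all singletons
  cl0 <- build_clusters(g, edges[0, ])
  expect_true(all(cl0$n_members == 1L))
})

test_that("clustering is invariant to sample input order", {
  set.seed(12)
  g <- matrix(sample(0:2, 10 * 80, TRUE), 10, 80)
  g[2, ] <- g[1, ]; g[7, ] <- g[6, ]
  rownames(g) <- sprintf("s%02d", 1:10)
  cl1 <- build_clusters(g, identity_edges(g))
  perm <- sample(nrow(g))
  g2 <- g[perm, ]
  cl2 <- build_clusters(g2, identity_edges(g2))
  expect_identical(cl1$canonical_sample, cl2$canonical_sample)
  expect_identical(cl1$members, cl2$members)
})

test_that("canonical sample has fewest missing loci with lexicographic ties", {
  g <- matrix(1L, 3, 80, dimnames = list(c("s3", "s1", "s2"), NULL))
  g["s3", 1:5] <- NA
  edges <- tibble::tibble(sample_a = c("s1", "s1"), sample_b = c("s2", "s3"),
                          shared_loci = 75L, matching_loci = 75L,
                          match_fraction = 1)
  cl <- build_clusters(g, edges)
  expect_equal(cl$canonical_sample, "s1")   # tie s1/s2 -> smallest id
})

test_that("cluster validation flags sex conflicts and opposite homozygotes", {
  g <- matrix(1L, 5, 80,
              dimnames = list(c("a1", "a2", "b1", "b2", "c1"), NULL))
  g["b2", 10] <- 0L; g["b1", 10] <- 2L      # opposite homozygotes
  clusters <- tibble::tibble(
    fish_id = c("C00001", "C00002", "C00003"),
    members = list(c("a1", "a2"), c("b1", "b2"), "c1"),
    n_members = c(2L, 2L, 1L),
    canonical_sample = c("a1", "b1", "c1"))
  samples <- tibble::tibble(
    sample_id = c("a1", "a2", "b1", "b2", "c1"),
    resolved_sex = c("F", "M", "M", "M", "F"),
    program = "P1", spawn_date = as.Date("2013-01-01"), spawn_year = 2013L)
  v <- validate_clusters(clusters, samples, g)
  expect_equal(v$report$n_sex_conflict, 1L)
  expect_equal(v$report$n_homozygote_conflict, 1L)
  expect_equal(v$clusters$fish_id, "C00003")
  # all-consistent cluster survives untouched
  expect_equal(v$clusters$resolved_sex, "F")
})

test_that("simulated multi-sample fish are recovered with no false merges", {
  cfg <- sim_config(programs = default_programs(80L), years = 2011:2014,
                    seed = 19)
  truth <- simulate_population(cfg)
  obs <- observe_population(truth, cfg)
  qc <- qc_pipeline(obs$samples, obs$genotypes, obs$panel)
  cl <- build_clusters(qc$genotypes, identity_edges(qc$genotypes))
  expect_equal(sum(cl$n_members), nrow(qc$genotypes))
  fish_of <- stats::setNames(obs$identity_map$fish_id, obs$identity_map$sample_id)
  fish_per_cluster <- vapply(cl$members,
                             function(m) length(unique(fish_of[m])), integer(1))
  expect_true(all(fish_per_cluster == 1L))  # no false merges
  retained <- rownames(qc$genotypes)
  # splits of a same-fish pair occur when genotyping error pushes its
  # mismatch count past the 5% band: P(Bin(L, ~4*eps) > 0.05 L), a few
  # percent per pair at eps = 0.005 -- the observed split count must stay
  # within that binomial expectation, and never exceed it wildly
  n_fish <- length(unique(fish_of[retained]))
  n_multi <- sum(table(fish_of[retained]) > 1)
  splits <- nrow(cl) - n_fish
  p_split <- 1 - stats::pbinom(floor(0.05 * 88), 88, 2 * 2 * 0.005 * 0.995)
  expect_lte(splits, stats::qbinom(0.999, n_multi, p_split) + 1)
})
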