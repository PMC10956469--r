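small_cfg <- function(...) {
  sim_config(programs = default_programs(60L), years = 2011:2014, seed = 101, ...)
}

test_that("founder frequencies are identical at zero divergence and seeded", {
  cfg <- small_cfg(lineage_fst = 0)
  f1 <- draw_founder_frequencies(cfg)
  f2 <- draw_founder_frequencies(cfg)
  expect_identical(f1, f2)
  expect_equal(f1$L1[names(f1$L1) != "Omy05inv"],
               f1$L2[names(f1$L2) != "Omy05inv"])
  expect_error(sim_config(lineage_fst = 1.2), "lineage_fst")
})

test_that("lineage divergence is recovered as Weir-Cockerham F_ST", {
  cfg <- sim_config(lineage_fst = 0.1, seed = 77)
  f <- draw_founder_frequencies(cfg)
  set.seed(1)
  auto <- setdiff(names(f$L1), "Omy05inv")
  ga <- sapply(f$L1[auto], function(p) rbinom(500, 2, p))
  gb <- sapply(f$L2[auto], function(p) rbinom(500, 2, p))
  theta <- pairwise_fst(ga, gb)$theta
  expect_gt(theta, 0.07)
  expect_lt(theta, 0.13)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(founder_freq_range = c(0, 0.8)))
  expect_error(sim_config(epsilon_sim = 0.6))
  bad_age <- default_age_dist()
  bad_age$L1$F <- c(0.5, 0.5, 0.5, 0, 0)
  expect_error(sim_config(age_at_return_dist = bad_age), "sum to 1")
  m <- matrix(0.3, 4, 4)
  expect_error(sim_config(stray_matrix = m), "stray_matrix")
})

test_that("no iteroparity or repeat spawning means one event per fish", {
  cfg <- small_cfg(
    iteroparity_prob = list(L1 = c(F = 0, M = 0), L2 = c(F = 0, M = 0)),
    repeat_spawn_prob = list(L1 = c(F = 0, M = 0), L2 = c(F = 0, M = 0)))
  truth <- simulate_population(cfg)
  expect_equal(max(table(truth$events$fish_id)), 1L)
})

test_that("identity stray matrix keeps all offspring at their natal program", {
  cfg <- small_cfg(stray_matrix = diag(4))
  truth <- simulate_population(cfg)
  ped <- truth$true_pedigree
  first_prog <- truth$events$program[match(ped$offspring_fish, truth$events$fish_id)]
  spawned <- !is.na(first_prog)
  expect_true(all(first_prog[spawned] == ped$mating_program[spawned]))
})

test_that("true offspring genotypes are Mendelian-consistent with parents", {
  cfg <- small_cfg()
  truth <- simulate_population(cfg)
  G <- truth$genotypes
  ped <- truth$true_pedigree
  auto <- seq_len(cfg$n_loci)
  ok <- vapply(seq_len(nrow(ped)), function(i) {
    go <- G[ped$offspring[i], auto]; gm <- G[ped$mother[i], auto]
    gf <- G[ped$father[i], auto]
    !any((gm == 0 & gf == 0 & go > 0) | (gm == 2 & gf == 2 & go < 2) |
         (gm == 0 & gf == 2 & go != 1) | (gm == 2 & gf == 0 & go != 1) |
         abs(go - gm / 2 - gf / 2) > 1)
  }, logical(1))
  expect_true(all(ok))
})

test_that("observation is deterministic under seed and applies stated error rates", {
  cfg <- small_cfg(missing_rate = 0.5, epsilon_sim = 0)
  truth <- simulate_population(cfg)
  o1 <- observe_population(truth, cfg)
  o2 <- observe_population(truth, cfg)
  expect_identical(o1$genotypes, o2$genotypes)
  expect_identical(o1$samples, o2$samples)
  # missing_rate = 0.5: mean called loci per sample ~ binomial L/2
  L <- ncol(o1$genotypes)
  called <- rowSums(!is.na(o1$genotypes))
  se <- sqrt(L * 0.25 / nrow(o1$genotypes))
  expect_lt(abs(mean(called) - L / 2), 4 * se)
})

test_that("with no genotyping error every true trio is Mendelian-compatible", {
  cfg <- small_cfg(epsilon_sim = 0, missing_rate = 0)
  truth <- simulate_population(cfg)
  obs <- observe_population(truth, cfg)
  G <- obs$genotypes
  map <- stats::setNames(obs$identity_map$sample_id, obs$identity_map$fish_id)
  ped <- truth$true_pedigree
  seen <- ped$offspring_fish %in% names(map) & ped$mother_fish %in% names(map) &
    ped$father_fish %in% names(map)
  ped <- ped[seen, ][1:min(50, sum(seen)), ]
  d <- per_marker_incompatibility_rate(
    tibble::tibble(offspring_fish = map[ped$offspring_fish],
                   mother_fish = map[ped$mother_fish],
                   father_fish = map[ped$father_fish]),
    G[, seq_len(cfg$n_loci)])
  expect_true(all(d$incompatibility_rate == 0))
})

test_that("observed allele frequencies converge to the simulating truth", {
  cfg <- sim_config(programs = default_programs(150L), years = 2011:2013,
                    seed = 5, lineage_fst = 0)
  truth <- simulate_population(cfg)
  obs <- observe_population(truth, cfg)
  auto <- sprintf("L%03d", seq_len(cfg$n_loci))
  af <- estimate_allele_freqs(obs$genotypes[, auto])
  # mixed cohorts drift from founder freqs; at fst = 0 both lineages share p
  p <- truth$allele_freqs$L1[auto]
  N <- nrow(obs$genotypes)
  within <- abs(af$freq - p) <= 4 * sqrt(p * (1 - p) / (2 * N)) + 0.03
  expect_gte(mean(within), 0.95)
})

test_that("genotype tables round-trip through the two-column CSV format", {
  cfg <- small_cfg()
  truth <- simulate_population(cfg)
  obs <- observe_population(truth, cfg)
  g <- obs$genotypes[1:40, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotype_csv(g, path, seed = cfg$seed)
  expect_identical(read_genotype_csv(path), g)
  expect_match(readLines(path, n = 1), "# seed: 101")
  spath <- withr::local_tempfile(fileext = ".csv")
  write_samples_csv(obs$samples[1:40, ], spath, seed = cfg$seed)
  back <- read_samples_csv(spath)
  expect_equal(back$sample_id, obs$samples$sample_id[1:40])
  expect_equal(back$spawn_date, obs$samples$spawn_date[1:40])
})
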