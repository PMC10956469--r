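# fish-level event table shared by the pool tests
pool_events <- function() {
  tibble::tibble(
    fish_id = c("M1", "F1", "M2", "F2", "IT", "K1"),
    program = c("P1", "P1", "P1", "P1", "P1", "P1"),
    spawn_date = as.Date(c("2013-01-05", "2013-01-05", "2013-01-10",
                           "2013-01-10", "2013-01-05", "2018-01-08")),
    spawn_year = c(2013L, 2013L, 2013L, 2013L, 2013L, 2018L),
    resolved_sex = c("M", "F", "M", "F", "F", "F"))
}

test_that("allele frequencies count gene copies and flag monomorphic loci", {
  g <- rbind(c(0L, 0L, 1L), c(1L, 0L, NA))   # {AA, AB} at locus 1
  colnames(g) <- c("a", "b", "c")
  af <- estimate_allele_freqs(g)
  expect_equal(af$freq[1], 0.25)             # p_alt; p_ref = 0.75
  expect_true(af$monomorphic[2])
  expect_equal(af$n_called[3], 1L)
  expect_null(names(af$freq))
})

test_that("candidate pools honor the allowed age gap across programs", {
  ev <- pool_events()
  pools <- build_candidate_pools(ev, "unconstrained",
                                 parentage_config(allowed_age_gap = c(2, 6)))
  # offspring of 2018 draw parents from 2012-2016: the 2013 spawners
  p18 <- pools[["2018"]]
  expect_setequal(p18$adults$fish_id, c("M1", "F1", "M2", "F2", "IT"))
  expect_equal(p18$n_pairs, choose(5, 2))
  # 2013 offspring have no parents on record
  expect_null(pools[["2013"]])
})

test_that("constrained pools require same program+date and opposite sexes", {
  ev <- pool_events()
  pools <- build_candidate_pools(ev, "constrained", parentage_config())
  prs <- pools[["2018"]]$pairs
  key <- paste(prs$fish_a, prs$fish_b)
  expect_setequal(key, c("F1 M1", "IT M1", "F2 M2"))
  # two females on a shared date never pair
  expect_false(any(prs$fish_a == "IT" & prs$fish_b == "F1"))
})

test_that("iteroparous adults enter the pool of every year they spawned", {
  ev <- pool_events()
  ev <- rbind(ev, tibble::tibble(
    fish_id = c("IT", "K2"), program = "P1",
    spawn_date = as.Date(c("2015-01-05", "2021-01-08")),
    spawn_year = c(2015L, 2021L), resolved_sex = c("F", "M")))
  pools <- build_candidate_pools(ev, "unconstrained", parentage_config())
  expect_true("IT" %in% pools[["2018"]]$adults$fish_id)   # via 2013 or 2015
  # 2021 offspring window is 2015-2019: IT qualifies via 2015 only
  expect_true("IT" %in% pools[["2021"]]$adults$fish_id)
  expect_false("M1" %in% pools[["2021"]]$adults$fish_id)
})

test_that("a Mendelian-perfect single pair is assigned as parent_pair", {
  set.seed(21)
  L <- 80
  p <- runif(L, 0.3, 0.7)
  gm <- rbinom(L, 2, p); gf <- rbinom(L, 2, p)
  go <- rbinom(L, 1, gm / 2) + rbinom(L, 1, gf / 2)
  geno <- rbind(M = gm, F = gf, K = go, X = rbinom(L, 2, p), Y = rbinom(L, 2, p))
  storage.mode(geno) <- "integer"
  colnames(geno) <- sprintf("L%03d", 1:L)
  ev <- tibble::tibble(
    fish_id = c("M", "F", "X", "Y", "K"), program = "P1",
    spawn_date = as.Date(c(rep("2013-01-05", 4), "2015-01-08")),
    spawn_year = c(rep(2013L, 4), 2015L),
    resolved_sex = c("F", "M", "F", "M", "F"))
  tt <- trio_tables(p, 0.005)
  pools <- build_candidate_pools(ev, "unconstrained", parentage_config())
  asg <- assign_parentage(geno, tibble::tibble(fish_id = "K",
                                               spawn_year = 2015L,
                                               program = "P1"),
                          pools, tt, parentage_config(min_loci_for_trio = 50))
  expect_equal(asg$map_category, "parent_pair")
  expect_setequal(c(asg$mother_fish, asg$father_fish), c("M", "F"))
  expect_equal(asg$n_incompatible, 0L)
  expect_gt(asg$lod, 5)
})

test_that("offspring with an empty pool are recorded unassignable", {
  g <- matrix(1L, 2, 60, dimnames = list(c("A", "B"), NULL))
  asg <- assign_parentage(
    g, tibble::tibble(fish_id = "A", spawn_year = 2013L, program = "P1"),
    list(), trio_tables(runif(60, .2, .8), 0.005), parentage_config())
  expect_equal(asg$map_category, "unassignable")
})

test_that("null best-LOD p-values are monotone in LOD and honest at the edges", {
  asg <- tibble::tibble(
    offspring_fish = c("a", "b", "c"), program = "P1",
    mother_fish = "m", father_fish = "f",
    lod = c(50, 2, -5), map_category = "parent_pair",
    n_loci = 80L, n_compatible = 80L, n_incompatible = 0L,
    pool_adults = 10L, pool_size = 45, spawn_year = 2015L)
  nb <- list("2015" = list(P1 = c(-3, -1, 0, 1, 3)))
  # a 5-draw null is deliberately coarser than the FDR threshold: warned
  expect_warning(out <- estimate_fdr(asg, nb, parentage_config(null_sim_size = 5)),
                 "resolution")
  expect_equal(out$p_value, c(0, 0.2, 1))
  expect_true(all(diff(out$q[order(-out$lod)]) >= 0))
  expect_true(out$accepted[1])
  expect_false(out$accepted[3])
})

test_that("run reconciliation follows the stated precedence rules", {
  mk <- function(off, mo, fa, q, accepted = TRUE) tibble::tibble(
    offspring_fish = off, mother_fish = mo, father_fish = fa,
    lod = 30, map_category = "parent_pair", q = q, accepted = accepted)
  con <- dplyr::bind_rows(
    mk("o1", "m1", "f1", 0.001),
    mk("o3", "m3", "f3", 0.002),
    mk("o4", "m4", "f4", 0.0001))
  unc <- dplyr::bind_rows(
    mk("o1", "m1", "f1", 0.001),     # same trio -> both_runs
    mk("o2", "m2", "f2", 0.003),     # only unconstrained
    mk("o3", "mx", "fx", 0.0001))    # conflict, lower q wins
  rec <- reconcile_runs(con, unc)
  ped <- rec$pedigree
  expect_equal(ped$provenance[ped$offspring_fish == "o1"], "both_runs")
  expect_equal(ped$provenance[ped$offspring_fish == "o2"], "unconstrained_only")
  expect_equal(ped$provenance[ped$offspring_fish == "o3"], "constrained_preferred")
  expect_equal(ped$mother_fish[ped$offspring_fish == "o3"], "mx")
  expect_equal(ped$provenance[ped$offspring_fish == "o4"], "constrained_only")
  expect_equal(nrow(rec$conflicts), 1L)
  # accounting identity
  expect_equal(nrow(ped), sum(table(ped$provenance)))
})

test_that("improbable trios are removed with named reasons", {
  ped <- tibble::tibble(
    offspring_fish = c("k1", "k2", "k3", "k4"),
    mother_fish = c("m1", "m2", "m3", "k4"),
    father_fish = c("f1", "f2", "f3", "f4"))
  ev <- tibble::tibble(
    fish_id = c("m1", "f1", "m2", "f2", "m3", "f3", "f4", "k1", "k2", "k3", "k4"),
    spawn_year = c(2013L, 2013L, 2013L, 2013L, 2015L, 2015L, 2013L,
                   2015L, 2015L, 2015L, 2015L))
  sex <- c(m1 = "F", f1 = "M", m2 = "M", f2 = "M", m3 = "F", f3 = "M",
           f4 = "M", k1 = "F", k2 = "F", k3 = "F", k4 = "F")
  out <- remove_improbable_trios(ped, ev, sex, parentage_config())
  expect_equal(out$pedigree$offspring_fish, "k1")
  expect_setequal(out$removals$reason[out$removals$offspring_fish == "k2"],
                  "sex_conflict")
  expect_setequal(out$removals$reason[out$removals$offspring_fish == "k3"],
                  "date_conflict")
  expect_setequal(out$removals$reason[out$removals$offspring_fish == "k4"],
                  "self_parent")
})

test_that("true parents dominate the single-parent LOD prescreen", {
  set.seed(33)
  L <- 90
  p <- runif(L, 0.2, 0.8)
  n_adults <- 150
  ga <- matrix(rbinom(n_adults * L, 2, rep(p, each = n_adults)), n_adults, L)
  gm <- ga[1, ]; gf <- ga[2, ]
  go <- rbinom(L, 1, gm / 2) + rbinom(L, 1, gf / 2)
  flip <- runif(L) < 0.005
  go[flip] <- pmin(2, pmax(0, go[flip] + sample(c(-1, 1), sum(flip), TRUE)))
  tt <- trio_tables(p, 0.005)
  lods <- po_weight_matrix(matrix(as.integer(go), 1), tt) %*%
    t(genotype_onehot(ga))
  expect_setequal(order(lods, decreasing = TRUE)[1:2], 1:2)
})
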