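lh_events <- function() {
  tibble::tibble(
    fish_id = c("A", "A", "B", "B", "C", "D", "D", "D"),
    sample_id = paste0("s", 1:8),
    program = c("P1", "P1", "P1", "P1", "P1", "P2", "P2", "P2"),
    spawn_date = as.Date(c("2013-01-05", "2013-02-10",   # same season
                           "2013-01-07", "2015-01-02",   # two seasons
                           "2013-01-09",
                           "2013-01-03", "2013-02-01", "2014-01-10")),
    spawn_year = c(2013L, 2013L, 2013L, 2015L, 2013L, 2013L, 2013L, 2014L),
    resolved_sex = c("F", "F", "F", "F", "M", "M", "M", "M"),
    cross_program = FALSE)
}

test_that("spawning use follows the within/across-season definitions", {
  u <- classify_spawn_use(lh_events())
  use <- stats::setNames(u$use, u$fish_id)
  expect_equal(use[["A"]], "repeat")
  expect_equal(use[["B"]], "iteroparous")
  expect_equal(use[["C"]], "once")
  expect_equal(use[["D"]], "repeat_and_iteroparous")
})

test_that("use table percentages recompute exactly from counts", {
  tab <- spawn_use_table(classify_spawn_use(lh_events()))
  tot <- tab[tab$sex == "Total", ]
  g <- split(tot, tot$program)
  for (d in g) expect_equal(d$pct, 100 * d$n / sum(d$n))
  # the combined label counts as iteroparous in the use-exclusive table
  expect_equal(tot$n[tot$program == "P2" & tot$use == "iteroparous"], 1L)
})

test_that("published-style use shares come straight from the count arithmetic", {
  counts <- tibble::tibble(
    program = "MRH",
    use = c("iteroparous", "once", "repeat"),
    n = c(364L, 1829L, 304L))
  out <- use_percentages(counts)
  expect_equal(out$pct[out$use == "iteroparous"], 100 * 364 / 2497,
               tolerance = 1e-10)
})

test_that("ages subtract the parents' mating season from the return season", {
  ev <- tibble::tibble(
    fish_id = c("m", "f", "k"), sample_id = paste0("s", 1:3),
    program = "P1",
    spawn_date = as.Date(c("2015-01-05", "2015-01-05", "2018-01-05")),
    spawn_year = c(2015L, 2015L, 2018L),
    resolved_sex = c("F", "M", "F"), length_mm = c(600, 610, 560))
  ped <- tibble::tibble(offspring_fish = "k", mother_fish = "m",
                        father_fish = "f")
  a <- tabulate_ages(ped, ev)
  expect_equal(a$records$age, 3)
  expect_equal(a$records$cohort_year, 2015)
  expect_equal(a$by_program_age$pct, 100)
})

test_that("iteroparous parents are dated by the shared season inside the gap", {
  ev <- tibble::tibble(
    fish_id = c("m", "m", "f", "k"), sample_id = paste0("s", 1:4),
    program = "P1",
    spawn_date = as.Date(c("2013-01-05", "2015-01-05", "2015-01-05",
                           "2017-01-05")),
    spawn_year = c(2013L, 2015L, 2015L, 2017L),
    resolved_sex = c("F", "F", "M", "M"), length_mm = NA_real_)
  ped <- tibble::tibble(offspring_fish = "k", mother_fish = "m",
                        father_fish = "f")
  a <- tabulate_ages(ped, ev)
  expect_equal(a$records$age, 2)   # shared year is 2015, not 2013
})

test_that("spawn-date bins are half-open and anchored per program season", {
  ev <- tibble::tibble(
    fish_id = letters[1:4], sample_id = paste0("s", 1:4), program = "P1",
    spawn_date = as.Date("2013-01-01") + c(0, 4, 5, 12),
    spawn_year = 2013L, resolved_sex = "F")
  b5 <- bin_spawn_dates(ev, 5L)
  expect_equal(as.integer(table(b5$events$bin_start)), c(2L, 1L, 1L))
  expect_equal(sort(unique(b5$events$bin_start)),
               as.Date("2013-01-01") + c(0, 5, 10))
  b10 <- bin_spawn_dates(ev, 10L)
  expect_equal(length(unique(b10$events$bin_start)), 2L)
})

test_that("straying rates are column percentages of the origin totals", {
  counts <- matrix(c(2L, 37L, 1704L, 182L), 4, 1,
                   dimnames = list(c("CH", "FRH", "MRH", "NH"), "MRH"))
  r <- straying_rates(counts)
  expect_equal(r["NH", "MRH"], 100 * 182 / 1925, tolerance = 1e-10)
  expect_equal(sum(r[, "MRH"]), 100)
})

test_that("straying matrix separates natal returns from strays", {
  ev <- tibble::tibble(
    fish_id = c("m", "f", "k1", "k2"), sample_id = paste0("s", 1:4),
    program = c("P1", "P1", "P1", "P2"),
    spawn_date = as.Date(c("2013-01-05", "2013-01-05", "2015-01-05",
                           "2015-01-06")),
    spawn_year = c(2013L, 2013L, 2015L, 2015L),
    resolved_sex = c("F", "M", "F", "M"))
  ped <- tibble::tibble(offspring_fish = c("k1", "k2"),
                        mother_fish = "m", father_fish = "f")
  s <- straying_matrix(ped, ev)
  expect_equal(s$counts["P1", "P1"], 1)
  expect_equal(s$counts["P2", "P1"], 1)
  expect_equal(sum(s$records$stray), 1)
})

test_that("reproductive success averages per event and per fish", {
  ev <- tibble::tibble(
    fish_id = c("m", "m", "f", "k1", "k2", "k3", "k4"),
    sample_id = paste0("s", 1:7), program = "P1",
    spawn_date = as.Date(c("2013-01-05", "2015-01-05", "2013-01-05",
                           "2015-01-05", "2015-01-06", "2017-01-05",
                           "2017-01-06")),
    spawn_year = c(2013L, 2015L, 2013L, 2015L, 2015L, 2017L, 2017L),
    resolved_sex = c("F", "F", "M", "F", "M", "F", "M"))
  # mother m: 3 offspring from 2013 mating, 1 from 2015 -> events 3 and 1
  ped <- tibble::tibble(
    offspring_fish = c("k1", "k2", "k3", "k4"),
    mother_fish = "m",
    father_fish = c("f", "f", "f", "f"))
  use <- classify_spawn_use(ev[ev$fish_id %in% c("m", "f"), ])
  rs <- reproductive_success(ped, ev, use)
  m_row <- rs$per_fish[rs$per_fish$fish_id == "m", ]
  expect_equal(m_row$total_offspring, 4L)
  itero_f <- rs$by_sex_use[rs$by_sex_use$sex == "F" &
                           rs$by_sex_use$use == "iteroparous", ]
  expect_equal(itero_f$mean_per_event, 2)   # events of 3 and 1
  expect_equal(itero_f$mean_total, 4)
})

test_that("1:2:1 segregation test matches the hand chi-square", {
  # counts (116, 233, 116), N = 465: chi-square ~ 0.00215
  obs <- c(116, 233, 116)
  e <- sum(obs) * c(.25, .5, .25)
  by_hand <- sum((obs - e)^2 / e)
  ct <- stats::chisq.test(obs, p = c(.25, .5, .25))
  expect_equal(unname(ct$statistic), by_hand, tolerance = 1e-10)
  expect_equal(unname(ct$parameter), 2L, ignore_attr = TRUE)
  # perfectly Mendelian counts: statistic 0, p 1
  ct0 <- stats::chisq.test(c(100, 200, 100), p = c(.25, .5, .25))
  expect_equal(unname(ct0$statistic), 0)
  expect_equal(ct0$p.value, 1)
})

test_that("omy05 summary classifies karyotypes and runs both test flavors", {
  set.seed(14)
  n <- 120
  fish <- sprintf("F%03d", 1:n)
  karyo <- stats::setNames(rep(1L, n), fish)   # all heterozygous parents
  ev <- tibble::tibble(
    fish_id = fish, sample_id = paste0("s", 1:n), program = "P1",
    spawn_date = as.Date("2013-01-05") + (seq_len(n) %% 20),
    spawn_year = 2013L,
    resolved_sex = rep(c("F", "M"), n / 2))
  kids <- sprintf("K%03d", 1:40)
  karyo_k <- stats::setNames(rbinom(40, 2, 0.5), kids)
  ev <- rbind(ev, tibble::tibble(
    fish_id = kids, sample_id = paste0("t", 1:40), program = "P1",
    spawn_date = as.Date("2015-01-05") + (seq_len(40) %% 20),
    spawn_year = 2015L, resolved_sex = rep(c("F", "M"), 20)))
  ped <- tibble::tibble(offspring_fish = kids,
                        mother_fish = fish[1:40], father_fish = fish[41:80])
  res <- omy05_summary(c(karyo, karyo_k), ev, ped)
  seg <- res$segregation
  expect_equal(seg$n[seg$group == "all"], 40L)
  expect_equal(seg$method[seg$group == "all"], "chi_square")
  # by-sex splits are small enough to trigger the exact substitute
  expect_true(all(seg$method[seg$group %in% c("F", "M")] %in%
                  c("chi_square", "exact_multinomial")))
  expect_true(all(res$hwe_by_program$p_value <= 1))
  f_tot <- res$freq_table[res$freq_table$sex_grp == "Total", ]
  expect_equal(sum(f_tot$n), 160L)
})

test_that("Kruskal-Wallis wrapper reproduces the hand rank computation", {
  r <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$H, 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2),
               tolerance = 1e-10)
  expect_equal(r$df, 1L, ignore_attr = TRUE)
  # identical groups: H = 0
  expect_equal(kruskal_wallis(rep(c(1, 2, 3), 2),
                              rep(c("a", "b"), each = 3))$H, 0)
  # degenerate input
  expect_equal(kruskal_wallis(rep(5, 6), rep(c("a", "b"), each = 3))$p_value, 1)
})

test_that("exact multinomial enumeration agrees with dmultinom tail sums", {
  p <- exact_multinomial_test(c(6, 2, 2), c(.25, .5, .25))
  # brute check on tiny n: enumerate directly
  n <- 10
  tot <- 0
  pobs <- stats::dmultinom(c(6, 2, 2), prob = c(.25, .5, .25))
  for (a in 0:n) for (b in 0:(n - a)) {
    pr <- stats::dmultinom(c(a, b, n - a - b), prob = c(.25, .5, .25))
    if (pr <= pobs * (1 + 1e-12)) tot <- tot + pr
  }
  expect_equal(p, tot)
  expect_lt(p, 0.05)
})
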