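make_panel <- function(n = 10, partial = integer()) {
  tibble::tibble(locus = sprintf("L%03d", seq_len(n)),
                 role = "autosomal_analysis",
                 typed_all_years = !(seq_len(n) %in% partial))
}

test_that("spawn seasons straddle the calendar boundary correctly", {
  d <- as.Date(c("2012-12-15", "2013-01-20", "2013-02-28", "2013-07-01",
                 "2012-06-30"))
  expect_equal(spawn_season(d), c(2013L, 2013L, 2013L, 2014L, 2012L))
})

test_that("locus selection drops partially typed and listed loci", {
  p <- make_panel(96, partial = 93:96)
  out <- select_loci(p, min_analysis_loci = 50)
  expect_equal(sum(out$role == "autosomal_analysis"), 92L)
  out2 <- select_loci(p, exclude = c("L001", "L002"), min_analysis_loci = 50)
  expect_equal(sum(out2$role == "autosomal_analysis"), 90L)
  expect_true(all(out2$role[out2$locus %in% c("L001", "L002")] == "excluded"))
  # unchanged when everything is typed and nothing excluded
  expect_identical(select_loci(make_panel(60)), make_panel(60))
  expect_error(select_loci(make_panel(96, partial = 1:60)), "minimum")
})

test_that("special markers never enter the autosomal panel", {
  p <- rbind(make_panel(5),
             tibble::tibble(locus = c("SexY", "Omy05inv"),
                            role = c("sex_marker", "omy05_marker"),
                            typed_all_years = TRUE))
  out <- select_loci(p, min_analysis_loci = 3)
  expect_false(any(out$role[out$locus %in% c("SexY", "Omy05inv")] ==
                   "autosomal_analysis"))
})

test_that("regenotype resolution keeps the most complete row, late ties win", {
  g <- rbind(c(0, 1, NA, NA), c(0, 1, 2, NA), c(1, 1, 1, 1),
             c(2, NA, 2, 0), c(0, NA, 1, 2))
  ids <- c("a", "a", "b", "c", "c")
  r <- resolve_regenotypes(g, ids)
  expect_equal(r$sample_ids, c("a", "b", "c"))
  expect_equal(unname(r$genotypes["a", ]), c(0, 1, 2, NA))  # fewer missing
  expect_equal(unname(r$genotypes["c", ]), c(0, NA, 1, 2))  # tie -> later row
  expect_true(r$log$tie[r$log$sample_id == "c"])
  expect_false(r$log$tie[r$log$sample_id == "a"])
})

test_that("missing-data filter implements the 82-of-92 rule", {
  g <- matrix(0L, 3, 92, dimnames = list(c("ok82", "ok92", "bad81"), NULL))
  g[1, 1:10] <- NA   # 82 calls -> retained
  g[3, 1:11] <- NA   # 81 calls -> removed
  f <- filter_missing(g, 0.10)
  expect_setequal(rownames(f$genotypes), c("ok82", "ok92"))
  expect_equal(f$removed, "bad81")
  # idempotent
  f2 <- filter_missing(f$genotypes, 0.10)
  expect_equal(nrow(f2$genotypes), 2L)
  expect_length(f2$removed, 0)
  # no missing data: zero removals
  expect_length(filter_missing(matrix(1L, 5, 92))$removed, 0)
})

test_that("sex resolution prefers genetic sex and removes double-unknowns", {
  r <- resolve_sex(c("M", "unknown", "unknown", "F"),
                   c("F", "F", "unknown", "F"))
  expect_equal(r$resolved_sex, c("M", "F", NA, "F"))
  expect_equal(r$removed, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(r$conflict, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(genetic_sex_from_marker(c(0L, 1L, 2L, NA)),
               c("F", "M", "M", "unknown"))
})

test_that("QC report reconciles and the removal fraction matches the binomial tail", {
  cfg <- sim_config(programs = default_programs(80L), years = 2011:2013,
                    seed = 31, missing_rate = 0.08,
                    phenotypic_sex_unknown_rate = 0.02)
  truth <- simulate_population(cfg)
  obs <- observe_population(truth, cfg)
  qc <- qc_pipeline(obs$samples, obs$genotypes, obs$panel)
  rep <- qc$report
  expect_equal(rep$n[rep$reason == "input"],
               sum(rep$n[rep$reason != "input"]))
  # removal prob = P(Binom(L, 0.08) > ceiling(0.1 L))
  L <- ncol(obs$genotypes)
  p_rm <- stats::pbinom(ceiling(0.1 * L), L, 0.08, lower.tail = FALSE)
  n <- rep$n[rep$reason == "input"]
  obs_rm <- rep$n[rep$reason == "removed_missing_data"]
  expect_lt(abs(obs_rm / n - p_rm), 4 * sqrt(p_rm * (1 - p_rm) / n) + 1e-3)
})
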