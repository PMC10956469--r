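#!/usr/bin/env Rscript

# Stage 5 — pedigree- and cluster-derived life-history tables.
#
# Spawning-use classification (once / repeat / iteroparous), age-at-spawning
# distributions by program and sex, 5-day spawn-date bins, the origin x
# return straying table, mean observed reproductive success by sex and use,
# inversion-karyotype frequencies with the 1:2:1 segregation test among
# offspring of heterozygous matings, and the rank tests for program and sex
# effects on multiple spawning.

suppressPackageStartupMessages({library(pbtped); library(dplyr)})

outdir <- "results/life_history"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

events <- utils::read.csv("results/qc/events.csv")
events$spawn_date <- as.Date(events$spawn_date)
events <- tibble::as_tibble(events)
ped <- utils::read.csv("results/pedigree/pedigree.csv")
fish_geno <- read_genotype_csv("results/qc/fish_genotypes.csv")

use <- classify_spawn_use(events)
tab <- spawn_use_table(use)
utils::write.csv(as.data.frame(tab), file.path(outdir, "spawn_use.csv"),
                 row.names = FALSE)
tot <- tab[tab$sex == "Total", ]
cat("spawning use (totals by program):\n")
print(as.data.frame(tidyr::pivot_wider(
  dplyr::mutate(tot, cell = sprintf("%d (%.1f%%)", n, pct))[, c("program", "use", "cell")],
  names_from = "program", values_from = "cell")))

ages <- tabulate_ages(ped, events)
utils::write.csv(as.data.frame(ages$by_program_age),
                 file.path(outdir, "age_by_program.csv"), row.names = FALSE)
utils::write.csv(as.data.frame(ages$by_program_sex_age),
                 file.path(outdir, "age_by_program_sex.csv"), row.names = FALSE)
utils::write.csv(as.data.frame(ages$size_at_age),
                 file.path(outdir, "size_at_age.csv"), row.names = FALSE)
cat(sprintf("ages assigned for %d offspring; censored return years: %s\n",
            nrow(ages$records), paste(ages$censored_return_years, collapse = " ")))

bins <- bin_spawn_dates(events, 5L)
utils::write.csv(as.data.frame(bins$counts),
                 file.path(outdir, "spawn_date_bins.csv"), row.names = FALSE)

stray <- straying_matrix(ped, events)
utils::write.csv(as.data.frame(stray$counts),
                 file.path(outdir, "straying_counts.csv"))
utils::write.csv(as.data.frame(round(stray$rates, 2)),
                 file.path(outdir, "straying_rates.csv"))
cat("straying rates (column % per origin program):\n")
print(round(stray$rates, 2))

rs <- reproductive_success(ped, events, use)
utils::write.csv(as.data.frame(rs$by_sex_use),
                 file.path(outdir, "reproductive_success.csv"), row.names = FALSE)

karyo <- fish_geno[, "Omy05inv"]
omy <- omy05_summary(karyo, events, ped)
utils::write.csv(as.data.frame(omy$freq_table),
                 file.path(outdir, "omy05_frequencies.csv"), row.names = FALSE)
utils::write.csv(as.data.frame(omy$segregation),
                 file.path(outdir, "omy05_segregation.csv"), row.names = FALSE)
cat("inversion segregation among offspring of AR x AR matings:\n")
print(as.data.frame(omy$segregation))

multi <- use[!is.na(use$sex), ]
prog1 <- vapply(multi$programs, `[[`, character(1), 1)
kw1 <- kruskal_wallis(as.integer(multi$use != "once"), prog1)
kw2 <- kruskal_wallis(as.integer(multi$use != "once"), multi$sex)
tests <- data.frame(
  test = c("multiple_spawning_by_program", "multiple_spawning_by_sex"),
  statistic = c(kw1$H, kw2$H), df = c(kw1$df, kw2$df),
  p_value = c(kw1$p_value, kw2$p_value))
utils::write.csv(tests, file.path(outdir, "tests.csv"), row.names = FALSE)
print(tests)
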