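#!/usr/bin/env Rscript

# Stage 3 — pedigree reconstruction.
#
# Two-pass parentage: a preliminary constrained run supplies accepted trios
# for per-marker Mendelian-incompatibility diagnostics; markers over the 2%
# incompatibility threshold are dropped; the final constrained (parents must
# share a recorded program+date and have opposite sexes) and unconstrained
# (same spawn year only) runs are reconciled, and improbable trios (sex or
# date conflicts, self-parentage) are removed.

suppressPackageStartupMessages({library(pbtped)})

qcdir <- "results/qc"
outdir <- "results/pedigree"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
seed <- 2026L

fish_geno <- read_genotype_csv(file.path(qcdir, "fish_genotypes.csv"))
events <- utils::read.csv(file.path(qcdir, "events.csv"))
events$spawn_date <- as.Date(events$spawn_date)
events <- tibble::as_tibble(events)
panel <- utils::read.csv("results/data/panel.csv")
analysis_loci <- intersect(panel$locus[panel$role == "autosomal_analysis"],
                           colnames(fish_geno))
geno <- fish_geno[, analysis_loci, drop = FALSE]
pcfg <- parentage_config()

prelim <- run_parentage(geno, events, "constrained", pcfg,
                        seed = child_seed(seed, "prelim"))
diag <- marker_diagnostics(prelim$assignments[prelim$assignments$accepted, ],
                           geno, estimate_allele_freqs(geno)$freq)
utils::write.csv(as.data.frame(diag), file.path(outdir, "marker_diagnostics.csv"),
                 row.names = FALSE)
bad <- diag$locus[diag$excluded]
cat(sprintf("preliminary run: %d accepted trios; %d marker(s) excluded (%s)\n",
            sum(prelim$assignments$accepted), length(bad),
            if (length(bad)) paste(bad, collapse = ", ") else "none"))

geno2 <- geno[, setdiff(analysis_loci, bad), drop = FALSE]
con <- run_parentage(geno2, events, "constrained", pcfg,
                     seed = child_seed(seed, "constrained"))
unc <- run_parentage(geno2, events, "unconstrained", pcfg,
                     seed = child_seed(seed, "unconstrained"))
rec <- reconcile_runs(con$assignments, unc$assignments)

ev1 <- events[!duplicated(events$fish_id), ]
sex_of <- stats::setNames(ev1$resolved_sex, ev1$fish_id)
fin <- remove_improbable_trios(rec$pedigree, events, sex_of, pcfg)

prov <- table(rec$pedigree$provenance)
cat("provenance of reconciled trios:\n"); print(prov)
cat(sprintf("improbable removals: %d; final pedigree: %d trios\n",
            nrow(fin$removals), nrow(fin$pedigree)))
stopifnot(nrow(fin$pedigree) == sum(prov) - nrow(fin$removals))

write_pedigree_files(fin$pedigree, file.path(outdir, "pedigree.csv"),
                     file.path(outdir, "pedigree_kid_pa_ma.txt"))
utils::write.csv(as.data.frame(fin$removals),
                 file.path(outdir, "improbable_removals.csv"), row.names = FALSE)

# recovery against the simulation truth
tped <- utils::read.csv("results/data/truth/true_pedigree.csv")
idmap <- utils::read.csv("results/data/truth/identity_map.csv")
clus <- utils::read.csv(file.path(qcdir, "clusters.csv"))
c2t <- stats::setNames(idmap$fish_id[match(clus$canonical_sample, idmap$sample_id)],
                       clus$fish_id)
key_true <- paste(tped$offspring_fish, pmin(tped$mother_fish, tped$father_fish),
                  pmax(tped$mother_fish, tped$father_fish))
ped <- fin$pedigree
key_got <- paste(c2t[ped$offspring_fish],
                 pmin(c2t[ped$mother_fish], c2t[ped$father_fish]),
                 pmax(c2t[ped$mother_fish], c2t[ped$father_fish]))
cat(sprintf("final trios matching simulation truth: %.1f%%\n",
            100 * mean(key_got %in% key_true)))
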