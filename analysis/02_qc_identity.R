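#!/usr/bin/env Rscript

# Stage 2 — quality control and identity resolution.
#
# Reads the raw tables from stage 1, removes samples missing too many locus
# calls, resolves each sample's sex (genetic marker first, phenotype as
# fallback), then collapses near-identical genotypes (>= 95% matching over
# co-called loci) into individual clusters: each cluster is one physical
# fish, possibly sampled in several seasons (iteroparous) or several times
# within one season (repeat spawner).

suppressPackageStartupMessages({library(pbtped)})

indir <- "results/data"
outdir <- "results/qc"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

geno <- read_genotype_csv(file.path(indir, "genotypes.csv"))
samples <- read_samples_csv(file.path(indir, "samples.csv"))
panel <- tibble::as_tibble(utils::read.csv(file.path(indir, "panel.csv")))

qc <- qc_pipeline(samples, geno, panel)
utils::write.csv(as.data.frame(qc$report), file.path(outdir, "qc_report.csv"),
                 row.names = FALSE)
print(as.data.frame(qc$report))

edges <- identity_edges(qc$genotypes)
clusters <- build_clusters(qc$genotypes, edges)
val <- validate_clusters(clusters, qc$samples, qc$genotypes)
events <- cluster_spawn_events(val$clusters, qc$samples)

cat(sprintf("%d samples -> %d clusters (%d multi-sample; %d removed for conflicts)\n",
            nrow(qc$genotypes), nrow(clusters), sum(clusters$n_members > 1),
            nrow(val$removed)))

utils::write.csv(data.frame(
  fish_id = val$clusters$fish_id,
  canonical_sample = val$clusters$canonical_sample,
  n_members = val$clusters$n_members,
  resolved_sex = val$clusters$resolved_sex,
  members = vapply(val$clusters$members, paste, character(1), collapse = ";")),
  file.path(outdir, "clusters.csv"), row.names = FALSE)
utils::write.csv(as.data.frame(events), file.path(outdir, "events.csv"),
                 row.names = FALSE)

# fish-level canonical genotypes over the analysis panel, for stage 3
keep <- qc$panel$locus[qc$panel$role != "excluded"]
fish_geno <- qc$genotypes[val$clusters$canonical_sample, keep, drop = FALSE]
rownames(fish_geno) <- val$clusters$fish_id
write_genotype_csv(fish_geno, file.path(outdir, "fish_genotypes.csv"))
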