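#!/usr/bin/env Rscript

# Stage 4 — population-genetic summaries.
#
# Observed/expected heterozygosity per program, pairwise Weir-Cockerham
# F_ST on a seeded 300-per-program subsample, a PCA of the same subsample,
# and the exact Hardy-Weinberg surface (heterozygote-excess D and exact
# p-value) of the inversion-indicator locus per program.

suppressPackageStartupMessages({library(pbtped); library(dplyr)})

outdir <- "results/popgen"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
seed <- 2026L

geno <- read_genotype_csv("results/data/genotypes.csv")
samples <- read_samples_csv("results/data/samples.csv")
panel <- utils::read.csv("results/data/panel.csv")
qc <- qc_pipeline(samples, geno, tibble::as_tibble(panel))
auto <- qc$panel$locus[qc$panel$role == "autosomal_analysis"]

het <- bind_rows(lapply(split(qc$samples$sample_id, qc$samples$program),
  function(ids) {
    h <- heterozygosity(qc$genotypes[ids, auto, drop = FALSE])
    tibble::tibble(Ho = h$Ho, He = h$He)
  }), .id = "program")
utils::write.csv(as.data.frame(het), file.path(outdir, "heterozygosity.csv"),
                 row.names = FALSE)
print(as.data.frame(het))

sub <- subsample_broodstock(qc$samples$sample_id, qc$samples$program, 300L,
                            seed = child_seed(seed, "subsample"))
by_prog <- split(qc$samples$sample_id, qc$samples$program)
progs <- sort(names(by_prog))
fst <- bind_rows(lapply(utils::combn(progs, 2, simplify = FALSE), function(pr) {
  th <- pairwise_fst(qc$genotypes[intersect(sub, by_prog[[pr[1]]]), auto],
                     qc$genotypes[intersect(sub, by_prog[[pr[2]]]), auto])$theta
  tibble::tibble(pop_a = pr[1], pop_b = pr[2], theta = th)
}))
utils::write.csv(as.data.frame(fst), file.path(outdir, "pairwise_fst.csv"),
                 row.names = FALSE)
cat("pairwise F_ST (Weir-Cockerham):\n"); print(as.data.frame(fst))

pca <- pca_genotypes(qc$genotypes[sub, auto], n_components = 4L)
utils::write.csv(data.frame(
  sample_id = rownames(pca$scores),
  program = qc$samples$program[match(rownames(pca$scores), qc$samples$sample_id)],
  pca$scores), file.path(outdir, "pca_scores.csv"), row.names = FALSE)

omy <- qc$panel$locus[qc$panel$role == "omy05_marker"]
hwe <- bind_rows(lapply(split(qc$samples$sample_id, qc$samples$program),
  function(ids) {
    g <- qc$genotypes[ids, omy]
    r <- hwe_exact(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                   sum(g == 2, na.rm = TRUE))
    tibble::tibble(n_AA = r$n_AA, n_AR = r$n_AB, n_RR = r$n_BB,
                   D = r$D, p_value = r$p_value)
  }), .id = "program")
utils::write.csv(as.data.frame(hwe), file.path(outdir, "omy05_hwe.csv"),
                 row.names = FALSE)
cat("inversion-locus HWE surface:\n"); print(as.data.frame(hwe))
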