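#' Pipeline configuration
#'
#' Exactly one of `simulation` (a [sim_config()]) or the `genotype_csv` +
#' `samples_csv` input paths must be supplied. All stage thresholds are
#' surfaced here with their standard defaults.
#'
#' @param simulation optional [sim_config()] block.
#' @param genotype_csv,samples_csv optional input table paths.
#' @param panel optional locus panel tibble (required with file inputs).
#' @param max_missing_frac QC missing-data threshold.
#' @param season_boundary month-day season boundary.
#' @param identity_threshold genotype match fraction for identity edges.
#' @param min_shared_loci minimum co-called loci for identity comparison.
#' @param parentage a [parentage_config()].
#' @param marker_exclude_rate incompatibility-rate exclusion threshold.
#' @param fst_subsample per-program subsample size for F_ST / PCA summaries.
#' @param seed global pipeline seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, genotype_csv = NULL,
                            samples_csv = NULL, panel = NULL,
                            max_missing_frac = 0.10,
                            season_boundary = "07-01",
                            identity_threshold = 0.95,
                            min_shared_loci = 60L,
                            parentage = parentage_config(),
                            marker_exclude_rate = 0.02,
                            fst_subsample = 300L,
                            seed = 1L) {
  has_sim <- !is.null(simulation)
  has_files <- !is.null(genotype_csv) || !is.null(samples_csv)
  if (has_sim == has_files)
    stop("exactly one of a simulation block or input file paths must be given")
  if (has_files && (is.null(genotype_csv) || is.null(samples_csv) || is.null(panel)))
    stop("file input requires genotype_csv, samples_csv and panel")
  structure(list(simulation = simulation, genotype_csv = genotype_csv,
                 samples_csv = samples_csv, panel = panel,
                 max_missing_frac = max_missing_frac,
                 season_boundary = season_boundary,
                 identity_threshold = identity_threshold,
                 min_shared_loci = as.integer(min_shared_loci),
                 parentage = parentage,
                 marker_exclude_rate = marker_exclude_rate,
                 fst_subsample = as.integer(fst_subsample),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> QC -> identity -> preliminary
#' parentage -> marker diagnostics -> final two-mode parentage ->
#' reconciliation and improbable-trio removal -> population-genetic and
#' life-history summaries. All tables are written as CSV under `outdir`; a
#' manifest records every output with its row count, and the accounting
#' identities (QC sample counts, cluster membership totals, pedigree
#' reconciliation arithmetic) are asserted before returning.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  emit <- function(name, df) {
    path <- file.path(outdir, paste0(name, ".csv"))
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    outputs[[name]] <<- nrow(df)
  }

  # ---- inputs ----
  if (!is.null(config$simulation)) {
    truth <- simulate_population(config$simulation)
    obs <- observe_population(truth, config$simulation)
    samples <- obs$samples
    geno <- obs$genotypes
    panel <- obs$panel
    write_truth_bundle(truth, obs$identity_map, file.path(outdir, "truth"))
  } else {
    geno <- read_genotype_csv(config$genotype_csv)
    samples <- read_samples_csv(config$samples_csv)
    panel <- config$panel
    truth <- NULL
  }

  # ---- QC ----
  qc <- qc_pipeline(samples, geno, panel,
                    max_missing_frac = config$max_missing_frac,
                    season_boundary = config$season_boundary)
  emit("qc_report", qc$report)

  # ---- identity ----
  edges <- identity_edges(qc$genotypes, threshold = config$identity_threshold,
                          min_shared_loci = config$min_shared_loci)
  clusters <- build_clusters(qc$genotypes, edges)
  stopifnot(sum(clusters$n_members) == nrow(qc$genotypes))  # accounting
  val <- validate_clusters(clusters, qc$samples, qc$genotypes)
  events <- cluster_spawn_events(val$clusters, qc$samples)
  emit("cluster_report", val$report)
  emit("clusters", tibble::tibble(
    fish_id = val$clusters$fish_id,
    canonical_sample = val$clusters$canonical_sample,
    n_members = val$clusters$n_members,
    resolved_sex = val$clusters$resolved_sex,
    members = vapply(val$clusters$members, paste, character(1), collapse = ";")))

  # ---- fish-level genotypes over analysis loci ----
  analysis_loci <- qc$panel$locus[qc$panel$role == "autosomal_analysis"]
  fish_geno <- qc$genotypes[val$clusters$canonical_sample, analysis_loci,
                            drop = FALSE]
  rownames(fish_geno) <- val$clusters$fish_id
  pcfg <- config$parentage

  # ---- preliminary parentage + marker diagnostics ----
  prelim <- run_parentage(fish_geno, events, "constrained", pcfg,
                          seed = child_seed(config$seed, "prelim"))
  prelim_ped <- prelim$assignments[prelim$assignments$accepted, , drop = FALSE]
  af <- estimate_allele_freqs(fish_geno)
  diag <- marker_diagnostics(prelim_ped, fish_geno, af$freq,
                             exclude_rate = config$marker_exclude_rate)
  emit("marker_diagnostics", diag)
  bad_loci <- diag$locus[diag$excluded]

  # ---- final parentage, both modes, on the cleaned panel ----
  fish_geno2 <- fish_geno[, setdiff(analysis_loci, bad_loci), drop = FALSE]
  con_run <- run_parentage(fish_geno2, events, "constrained", pcfg,
                           seed = child_seed(config$seed, "constrained"))
  unc_run <- run_parentage(fish_geno2, events, "unconstrained", pcfg,
                           seed = child_seed(config$seed, "unconstrained"))
  rec <- reconcile_runs(con_run$assignments, unc_run$assignments)
  sex_of <- stats::setNames(val$clusters$resolved_sex, val$clusters$fish_id)
  fin <- remove_improbable_trios(rec$pedigree, events, sex_of, pcfg)
  pedigree <- fin$pedigree
  prov <- table(factor(rec$pedigree$provenance,
                       c("both_runs", "unconstrained_only",
                         "constrained_preferred", "constrained_only")))
  stopifnot(nrow(pedigree) == sum(prov) - nrow(fin$removals))  # accounting
  write_pedigree_files(pedigree, file.path(outdir, "pedigree.csv"),
                       file.path(outdir, "pedigree_kid_pa_ma.txt"))
  outputs[["pedigree"]] <- nrow(pedigree)
  emit("pedigree_provenance",
       tibble::tibble(provenance = names(prov), n = as.integer(prov)))
  emit("improbable_removals", fin$removals)

  # ---- population genetics ----
  by_prog <- split(qc$samples$sample_id, qc$samples$program)
  het <- dplyr::bind_rows(lapply(names(by_prog), function(p) {
    h <- heterozygosity(qc$genotypes[by_prog[[p]], analysis_loci, drop = FALSE])
    tibble::tibble(program = p, Ho = h$Ho, He = h$He)
  }))
  emit("heterozygosity", het)
  sub <- subsample_broodstock(qc$samples$sample_id, qc$samples$program,
                              config$fst_subsample,
                              seed = child_seed(config$seed, "subsample"))
  progs <- sort(unique(qc$samples$program))
  fst <- dplyr::bind_rows(lapply(utils::combn(progs, 2, simplify = FALSE),
    function(pr) {
      ga <- qc$genotypes[intersect(sub, by_prog[[pr[1]]]), analysis_loci, drop = FALSE]
      gb <- qc$genotypes[intersect(sub, by_prog[[pr[2]]]), analysis_loci, drop = FALSE]
      tibble::tibble(pop_a = pr[1], pop_b = pr[2],
                     theta = pairwise_fst(ga, gb)$theta)
    }))
  emit("pairwise_fst", fst)
  pca <- pca_genotypes(qc$genotypes[sub, analysis_loci, drop = FALSE],
                       n_components = 4L)
  emit("pca_scores", tibble::tibble(
    sample_id = rownames(pca$scores),
    program = qc$samples$program[match(rownames(pca$scores), qc$samples$sample_id)],
    PC1 = pca$scores[, 1], PC2 = pca$scores[, 2]))

  # ---- life history ----
  use_rec <- classify_spawn_use(events)
  emit("spawn_use", spawn_use_table(use_rec))
  ages <- tabulate_ages(pedigree, events, pcfg$allowed_age_gap)
  emit("age_by_program", ages$by_program_age)
  emit("age_by_program_sex", ages$by_program_sex_age)
  emit("size_at_age", ages$size_at_age)
  stray <- straying_matrix(pedigree, events, pcfg$allowed_age_gap)
  emit("straying_counts", as.data.frame(stray$counts))
  emit("straying_rates", as.data.frame(round(stray$rates, 2)))
  rs <- reproductive_success(pedigree, events, use_rec, pcfg$allowed_age_gap)
  emit("reproductive_success", rs$by_sex_use)
  omy_locus <- qc$panel$locus[qc$panel$role == "omy05_marker"]
  omy <- NULL
  if (length(omy_locus) == 1) {
    karyo <- qc$genotypes[val$clusters$canonical_sample, omy_locus]
    names(karyo) <- val$clusters$fish_id
    omy <- omy05_summary(karyo, events, pedigree)
    emit("omy05_frequencies", omy$freq_table)
    emit("omy05_hwe", omy$hwe_by_program)
    emit("omy05_segregation", omy$segregation)
  }

  # ---- statistical tests (program/sex effects on multiple-spawning) ----
  multi <- use_rec[!is.na(use_rec$sex), ]
  multi$is_multiple <- as.integer(multi$use != "once")
  prog1 <- vapply(multi$programs, function(p) p[[1]], character(1))
  kw_prog <- kruskal_wallis(multi$is_multiple, prog1)
  kw_sex <- kruskal_wallis(multi$is_multiple, multi$sex)
  emit("tests", tibble::tibble(
    test = c("multiple_spawning_by_program", "multiple_spawning_by_sex"),
    statistic = c(kw_prog$H, kw_sex$H),
    df = c(kw_prog$df, kw_sex$df),
    p_value = c(kw_prog$p_value, kw_sex$p_value)))

  manifest <- tibble::tibble(output = names(outputs),
                             n_rows = unlist(outputs),
                             seed = config$seed)
  utils::write.csv(as.data.frame(manifest), file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(truth = truth, qc = qc, clusters = val, events = events,
                 marker_diag = diag, constrained = con_run$assignments,
                 unconstrained = unc_run$assignments,
                 reconciliation = rec, pedigree = pedigree,
                 removals = fin$removals, heterozygosity = het, fst = fst,
                 spawn_use = use_rec, ages = ages, straying = stray,
                 reproductive_success = rs, omy05 = omy, manifest = manifest))
}
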