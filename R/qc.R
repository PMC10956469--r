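#' Select the analysis locus panel
#'
#' Retains loci typed in all study years; loci that are not are re-tagged
#' `excluded`. The Y-linked sex marker and the inversion-indicator locus keep
#' their special roles and never enter the autosomal analysis panel. An
#' exclusion list (e.g. loci flagged by [marker_diagnostics()]) may be
#' supplied and is applied on top.
#'
#' @param panel tibble with `locus`, `role`, `typed_all_years`.
#' @param exclude character vector of locus ids to force-exclude.
#' @param min_analysis_loci hard minimum of retained analysis loci.
#' @return the panel with updated `role`.
#' @export
select_loci <- function(panel, exclude = character(), min_analysis_loci = 50L) {
  stopifnot(all(c("locus", "role", "typed_all_years") %in% names(panel)))
  out <- panel
  out$role[!out$typed_all_years] <- "excluded"
  out$role[out$locus %in% exclude] <- "excluded"
  n <- sum(out$role == "autosomal_analysis")
  if (n < min_analysis_loci)
    stop(sprintf("only %d analysis loci retained (minimum %d)", n, min_analysis_loci))
  out
}

#' Resolve re-genotyped samples to one genotype per sample ID
#'
#' When a sample ID carries several genotype rows (re-genotyping after an
#' initial low-quality run), the row with the fewest missing loci is kept;
#' ties are broken toward the latest-loaded row and logged.
#'
#' @param geno genotype matrix (rows in load order, 0/1/2/NA).
#' @param sample_ids sample ID per row (may repeat).
#' @return list with `genotypes` (one row per unique ID, rownames set),
#'   `sample_ids`, and `log` (tibble of resolved duplicates).
#' @export
resolve_regenotypes <- function(geno, sample_ids) {
  stopifnot(nrow(geno) == length(sample_ids))
  n_miss <- rowSums(is.na(geno))
  ord <- seq_along(sample_ids)
  pick <- tapply(ord, sample_ids, function(idx) {
    m <- n_miss[idx]
    idx[max(which(m == min(m)))]        # tie -> latest load order
  })
  pick <- pick[match(unique(sample_ids), names(pick))]
  dup_ids <- unique(sample_ids[duplicated(sample_ids)])
  log <- tibble::tibble(
    sample_id = dup_ids,
    n_rows = vapply(dup_ids, function(s) sum(sample_ids == s), integer(1)),
    tie = vapply(dup_ids, function(s) {
      m <- n_miss[sample_ids == s]
      sum(m == min(m)) > 1
    }, logical(1))
  )
  out <- geno[as.integer(pick), , drop = FALSE]
  rownames(out) <- names(pick)
  list(genotypes = out, sample_ids = names(pick), log = log)
}

#' Remove samples with too much missing data
#'
#' A sample is retained when its number of missing calls over the analysis
#' and special loci is at most `ceiling(max_missing_frac * L)`. With a
#' 92-locus panel and the default 10% threshold this retains samples with at
#' least 82 successful calls.
#'
#' @param geno genotype matrix over the panel loci.
#' @param max_missing_frac maximum tolerated missing fraction.
#' @return list with `genotypes` (retained rows), `removed` (sample ids) and
#'   `report` tibble.
#' @export
filter_missing <- function(geno, max_missing_frac = 0.10) {
  L <- ncol(geno)
  n_miss <- rowSums(is.na(geno))
  keep <- n_miss <= ceiling(max_missing_frac * L)
  list(genotypes = geno[keep, , drop = FALSE],
       removed = rownames(geno)[!keep],
       report = tibble::tibble(n_input = nrow(geno),
                               n_retained = sum(keep),
                               n_removed = sum(!keep),
                               min_calls = L - ceiling(max_missing_frac * L)))
}

#' Genetic sex from the Y-linked marker genotype
#'
#' The marker is hemizygous-like: females carry no Y allele (genotype 0),
#' males one (genotype 1). Any observed Y dosage >= 1 is called male;
#' 0 female; missing unknown.
#'
#' @param sex_marker_geno integer vector (0/1/2/NA).
#' @return character vector in `{F, M, unknown}`.
#' @export
genetic_sex_from_marker <- function(sex_marker_geno) {
  out <- ifelse(is.na(sex_marker_geno), "unknown",
                ifelse(sex_marker_geno >= 1L, "M", "F"))
  out
}

#' Resolve sex from genetic and phenotypic records
#'
#' Genetic sex takes precedence; phenotypic sex is used when the genetic call
#' is unknown; samples with neither are flagged for removal.
#' Genetic/phenotypic conflicts are resolved in favor of genetic sex and
#' returned in the conflict log.
#'
#' @param genetic,phenotypic character vectors in `{F, M, unknown}` (or `NA`
#'   treated as unknown).
#' @return list with `resolved_sex` (`NA` where unresolvable), `removed`
#'   (logical), and `conflict` (logical log).
#' @export
resolve_sex <- function(genetic, phenotypic) {
  genetic[is.na(genetic)] <- "unknown"
  phenotypic[is.na(phenotypic)] <- "unknown"
  resolved <- ifelse(genetic != "unknown", genetic,
                     ifelse(phenotypic != "unknown", phenotypic, NA_character_))
  list(resolved_sex = resolved,
       removed = is.na(resolved),
       conflict = genetic != "unknown" & phenotypic != "unknown" &
         genetic != phenotypic)
}

#' Run the full genotype/metadata quality-control stage
#'
#' Applies, in order: locus selection, re-genotype resolution, the
#' missing-data filter, spawn-season labeling, and sex resolution. The
#' returned report reconciles exactly: input = retained + removed per
#' disjoint reason.
#'
#' @param samples metadata tibble with `sample_id`, `program`, `spawn_date`,
#'   `phenotypic_sex`, and optional `length_mm`, `adipose_present`.
#' @param geno genotype matrix with sample rownames (possibly duplicated
#'   sample IDs handled beforehand via [resolve_regenotypes()]).
#' @param panel locus panel tibble.
#' @param max_missing_frac missing-data threshold.
#' @param exclude_loci loci to drop from the analysis panel.
#' @param season_boundary month-day season boundary for [spawn_season()].
#' @return list with `samples` (retained, with `spawn_year`, `genetic_sex`,
#'   `resolved_sex`), `genotypes`, `panel`, `report`, `sex_conflicts`.
#' @export
qc_pipeline <- function(samples, geno, panel, max_missing_frac = 0.10,
                        exclude_loci = character(), season_boundary = "07-01") {
  panel <- select_loci(panel, exclude = exclude_loci)
  keep_loci <- panel$locus[panel$role != "excluded"]
  geno <- geno[, keep_loci, drop = FALSE]
  stopifnot(!is.null(rownames(geno)), all(samples$sample_id %in% rownames(geno)))
  geno <- geno[samples$sample_id, , drop = FALSE]
  n_input <- nrow(samples)

  fm <- filter_missing(geno, max_missing_frac)
  geno <- fm$genotypes
  samples <- samples[samples$sample_id %in% rownames(geno), , drop = FALSE]

  samples$spawn_year <- spawn_season(samples$spawn_date, season_boundary)
  sex_locus <- panel$locus[panel$role == "sex_marker"]
  genetic <- if (length(sex_locus) == 1) {
    genetic_sex_from_marker(geno[samples$sample_id, sex_locus])
  } else rep("unknown", nrow(samples))
  rs <- resolve_sex(genetic, samples$phenotypic_sex)
  samples$genetic_sex <- genetic
  samples$resolved_sex <- rs$resolved_sex
  removed_sex <- samples$sample_id[rs$removed]
  samples <- samples[!rs$removed, , drop = FALSE]
  geno <- geno[samples$sample_id, , drop = FALSE]

  report <- tibble::tibble(
    reason = c("input", "removed_missing_data", "removed_no_sex", "retained"),
    n = c(n_input, length(fm$removed), length(removed_sex), nrow(samples))
  )
  stopifnot(report$n[1] == sum(report$n[2:4]))
  list(samples = samples, genotypes = geno, panel = panel, report = report,
       sex_conflicts = samples$sample_id[rs$conflict[!rs$removed]])
}
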