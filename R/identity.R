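#' Genotype match fraction between two samples
#'
#' Compares unordered diploid calls at loci called in both samples. Returns
#' `NULL` (no edge) when fewer than `min_shared_loci` loci are co-called.
#'
#' @param g1,g2 integer genotype vectors (0/1/2/NA) on the same panel.
#' @param min_shared_loci minimum co-called loci for a comparison.
#' @return list with `shared_loci`, `matching_loci`, `match_fraction`, or
#'   `NULL`.
#' @export
match_fraction <- function(g1, g2, min_shared_loci = 60L) {
  shared <- !is.na(g1) & !is.na(g2)
  if (sum(shared) < min_shared_loci) return(NULL)
  matching <- sum(g1[shared] == g2[shared])
  list(shared_loci = sum(shared), matching_loci = matching,
       match_fraction = matching / sum(shared))
}

#' All near-identical sample pairs
#'
#' Computes, for every sample pair, the number of co-called loci and the
#' number of matching unordered genotypes via one-hot crossproducts (exact,
#' all pairs), and returns the pairs whose match fraction meets the identity
#' threshold with at least `min_shared_loci` co-called loci.
#'
#' @param geno genotype matrix (samples x loci, rownames = sample ids).
#' @param threshold minimum match fraction for an identity edge.
#' @param min_shared_loci minimum co-called loci.
#' @return tibble with `sample_a`, `sample_b`, `shared_loci`,
#'   `matching_loci`, `match_fraction` (a < b lexicographically).
#' @export
identity_edges <- function(geno, threshold = 0.95, min_shared_loci = 60L) {
  n <- nrow(geno)
  ids <- rownames(geno)
  S <- genotype_onehot(geno)
  M <- tcrossprod(S)                         # matching co-called loci
  called <- (!is.na(geno)) + 0
  C <- tcrossprod(called)                    # co-called loci
  hit <- which(upper.tri(C) & C >= min_shared_loci & M >= threshold * C,
               arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(tibble::tibble(sample_a = character(), sample_b = character(),
                          shared_loci = integer(), matching_loci = integer(),
                          match_fraction = numeric()))
  }
  a <- ids[hit[, 1]]; b <- ids[hit[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- tibble::tibble(sample_a = a, sample_b = b,
                        shared_loci = as.integer(C[hit]),
                        matching_loci = as.integer(round(M[hit])),
                        match_fraction = M[hit] / C[hit])
  dplyr::arrange(out, .data$sample_a, .data$sample_b)
}

#' Collapse samples into individual clusters
#'
#' Samples joined by identity edges form connected components, each
#' representing one physical fish; samples with no edge become singleton
#' clusters. The canonical sample of a cluster is the member with the fewest
#' missing loci (ties broken toward the lexicographically smallest sample
#' ID), and cluster IDs are assigned deterministically from sorted canonical
#' samples, so the clustering is invariant to input order.
#'
#' @param geno genotype matrix (samples x loci).
#' @param edges tibble from [identity_edges()].
#' @return tibble with `fish_id`, `members` (list column), `n_members`,
#'   `canonical_sample`.
#' @export
build_clusters <- function(geno, edges) {
  ids <- sort(rownames(geno))
  g <- igraph::graph_from_data_frame(edges[, c("sample_a", "sample_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  n_miss <- rowSums(is.na(geno))[ids]
  members <- split(ids, comp$membership)
  canon <- vapply(members, function(m) {
    m <- sort(m)
    m[which.min(n_miss[m])]
  }, character(1))
  ord <- order(canon)
  members_sorted <- lapply(members[ord], sort)
  tibble::tibble(
    fish_id = sprintf("C%05d", seq_along(ord)),
    members = unname(members_sorted),
    n_members = unname(lengths(members_sorted)),
    canonical_sample = unname(canon[ord])
  )
}

#' Validate clusters for sex and genotype consistency
#'
#' A cluster is removed when its members' resolved sexes disagree, or when
#' any two members are called as opposite homozygotes at any locus (an
#' identity-breaking conflict). Valid clusters receive the consensus
#' `resolved_sex`.
#'
#' @param clusters tibble from [build_clusters()].
#' @param samples QC'd sample tibble (with `sample_id`, `resolved_sex`,
#'   `program`, `spawn_date`, `spawn_year`).
#' @param geno genotype matrix.
#' @return list with `clusters` (valid, with `resolved_sex` and spawn-event
#'   counts), `removed` (with `status`), `report`.
#' @export
validate_clusters <- function(clusters, samples, geno) {
  sex_of <- stats::setNames(samples$resolved_sex, samples$sample_id)
  status <- vapply(clusters$members, function(m) {
    sx <- unique(sex_of[m])
    sx <- sx[!is.na(sx)]
    if (length(sx) > 1) return("removed_sex_conflict")
    if (length(m) > 1) {
      gm <- geno[m, , drop = FALSE]
      has0 <- colSums(gm == 0, na.rm = TRUE) > 0
      has2 <- colSums(gm == 2, na.rm = TRUE) > 0
      if (any(has0 & has2)) return("removed_homozygote_conflict")
    }
    "valid"
  }, character(1))
  clusters$status <- status
  clusters$resolved_sex <- vapply(clusters$members, function(m) {
    sx <- unique(sex_of[m]); sx <- sx[!is.na(sx)]
    if (length(sx) == 1) sx else NA_character_
  }, character(1))
  report <- tibble::tibble(
    n_clusters = nrow(clusters),
    n_valid = sum(status == "valid"),
    n_sex_conflict = sum(status == "removed_sex_conflict"),
    n_homozygote_conflict = sum(status == "removed_homozygote_conflict")
  )
  list(clusters = clusters[status == "valid", , drop = FALSE],
       removed = clusters[status != "valid", , drop = FALSE],
       report = report)
}

#' Spawn events per individual cluster
#'
#' Expands valid clusters to one row per member spawn event, carrying the
#' program, date and season. Fish with events at more than one program are
#' flagged `cross_program`.
#'
#' @param clusters valid clusters from [validate_clusters()].
#' @param samples QC'd sample tibble.
#' @return tibble with `fish_id`, `sample_id`, `program`, `spawn_date`,
#'   `spawn_year`, `resolved_sex`, `cross_program`.
#' @export
cluster_spawn_events <- function(clusters, samples) {
  long <- tibble::tibble(
    fish_id = rep(clusters$fish_id, clusters$n_members),
    sample_id = unlist(clusters$members, use.names = FALSE)
  )
  out <- dplyr::left_join(long, samples[, intersect(
    c("sample_id", "program", "spawn_date", "spawn_year", "length_mm"),
    names(samples))], by = "sample_id")
  out <- dplyr::left_join(out,
    tibble::tibble(fish_id = clusters$fish_id, resolved_sex = clusters$resolved_sex),
    by = "fish_id")
  out <- dplyr::group_by(out, .data$fish_id)
  out <- dplyr::mutate(out, cross_program = dplyr::n_distinct(.data$program) > 1)
  dplyr::ungroup(out)
}
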