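#' Write a genotype table in two-column-per-locus CSV format
#'
#' One row per sample; for each locus two columns `<locus>` and `<locus>_1`
#' holding the two allele calls (`A`/`B`), with `0` in both columns for a
#' missing call — the layout of common two-column SNP genotype tables.
#'
#' @param geno genotype matrix (samples x loci, 0/1/2/NA).
#' @param path output CSV path.
#' @param seed optional seed recorded in a `#` header comment.
#' @export
write_genotype_csv <- function(geno, path, seed = NULL) {
  L <- ncol(geno)
  a1 <- ifelse(is.na(geno), "0", ifelse(geno >= 1, "B", "A"))
  a2 <- ifelse(is.na(geno), "0", ifelse(geno == 2, "B", "A"))
  out <- matrix("", nrow(geno), 2 * L)
  out[, seq(1, 2 * L, 2)] <- a2   # first allele: B only for hom alt
  out[, seq(2, 2 * L, 2)] <- a1
  # genotype 1 (het) -> A,B; 2 -> B,B; 0 -> A,A
  colnames(out) <- as.vector(rbind(colnames(geno), paste0(colnames(geno), "_1")))
  df <- data.frame(sample_id = rownames(geno), out, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

#' Read a two-column-per-locus genotype CSV
#'
#' @param path CSV path as written by [write_genotype_csv()].
#' @return genotype matrix (0/1/2/NA) with sample rownames.
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        colClasses = "character")
  ids <- df$sample_id
  m <- as.matrix(df[, -1, drop = FALSE])
  loci <- colnames(m)[seq(1, ncol(m), 2)]
  g1 <- m[, seq(1, ncol(m), 2), drop = FALSE]
  g2 <- m[, seq(2, ncol(m), 2), drop = FALSE]
  geno <- (g1 == "B") + (g2 == "B")
  geno[g1 == "0" | g2 == "0"] <- NA_integer_
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(ids, loci)
  geno
}

#' Write / read the sample metadata table
#'
#' @param samples metadata tibble.
#' @param path CSV path.
#' @param seed optional seed recorded in a header comment.
#' @export
write_samples_csv <- function(samples, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  utils::write.csv(as.data.frame(samples), con, row.names = FALSE, quote = FALSE)
}

#' @rdname write_samples_csv
#' @return for `read_samples_csv`, the metadata tibble.
#' @export
read_samples_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df$spawn_date <- as.Date(df$spawn_date)
  tibble::as_tibble(df)
}

#' Write a pedigree as CSV and as a kid/pa/ma flat file
#'
#' @param pedigree accepted-trio tibble.
#' @param csv_path full pedigree CSV (offspring, parents, lod, q,
#'   provenance).
#' @param flat_path three-column whitespace-delimited kid/pa/ma file for
#'   interoperability with common pedigree tools.
#' @export
write_pedigree_files <- function(pedigree, csv_path, flat_path) {
  keep <- intersect(c("offspring_fish", "mother_fish", "father_fish", "lod",
                      "q", "provenance", "map_category", "n_incompatible"),
                    names(pedigree))
  utils::write.csv(as.data.frame(pedigree[, keep]), csv_path, row.names = FALSE)
  flat <- data.frame(kid = pedigree$offspring_fish,
                     pa = pedigree$father_fish,
                     ma = pedigree$mother_fish)
  utils::write.table(flat, flat_path, row.names = FALSE, quote = FALSE)
}

#' Write a simulation truth bundle as plain-text files
#'
#' The true pedigree and identity map as CSV and the configuration echo as
#' JSON.
#'
#' @param truth a `truth_bundle`.
#' @param identity_map sample-to-fish map from [observe_population()].
#' @param dir output directory (created if needed).
#' @export
write_truth_bundle <- function(truth, identity_map, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(
    truth$true_pedigree[, c("offspring_fish", "mother_fish", "father_fish",
                            "mating_year", "mating_program")]),
    file.path(dir, "true_pedigree.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(identity_map),
                   file.path(dir, "identity_map.csv"), row.names = FALSE)
  cfg <- unclass(truth$config)
  cfg$programs <- as.data.frame(cfg$programs)
  cfg$stray_matrix <- as.data.frame(cfg$stray_matrix)
  jsonlite::write_json(cfg, file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
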