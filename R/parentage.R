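#' Parentage configuration
#'
#' @param epsilon per-gene-copy genotyping error rate assumed by the trio
#'   likelihood.
#' @param fdr_threshold q-value acceptance threshold.
#' @param allowed_age_gap inclusive range of offspring ages (offspring spawn
#'   year minus parent spawn year).
#' @param null_sim_size simulated unrelated offspring per offspring-year
#'   stratum for the Monte-Carlo null of the best-pair LOD; each is
#'   evaluated against the stratum's full candidate pool, so the implied
#'   number of simulated unrelated trios is `null_sim_size` times the pool
#'   size.
#' @param min_loci_for_trio minimum loci co-called in all three members.
#' @param top_k candidate parents retained per offspring by the
#'   single-parent LOD prescreen before exact trio evaluation.
#' @return a `parentage_config` list.
#' @export
parentage_config <- function(epsilon = 0.005, fdr_threshold = 0.01,
                             allowed_age_gap = c(2L, 6L),
                             null_sim_size = 500L,
                             allele_freq_source = c("per_program", "pooled"),
                             min_loci_for_trio = 50L,
                             top_k = 15L) {
  stopifnot(epsilon > 0, epsilon < 0.5,
            fdr_threshold > 0, fdr_threshold <= 1,
            allowed_age_gap[1] >= 1, diff(allowed_age_gap) >= 0)
  structure(list(epsilon = epsilon, fdr_threshold = fdr_threshold,
                 allowed_age_gap = as.integer(allowed_age_gap),
                 null_sim_size = as.integer(null_sim_size),
                 allele_freq_source = match.arg(allele_freq_source),
                 min_loci_for_trio = as.integer(min_loci_for_trio),
                 top_k = as.integer(top_k)),
            class = "parentage_config")
}

#' Allele frequencies from adult genotypes
#'
#' Frequency of the alternate allele as allele count over called gene
#' copies, per locus. Monomorphic loci (and loci with no calls) are flagged;
#' they are excluded from LOD computation by [trio_tables()].
#'
#' @param geno genotype matrix (0/1/2/NA).
#' @return tibble with `locus`, `freq`, `n_called`, `monomorphic`.
#' @export
estimate_allele_freqs <- function(geno) {
  n_called <- unname(colSums(!is.na(geno)))
  freq <- ifelse(n_called > 0, unname(colSums(geno, na.rm = TRUE)) / (2 * n_called),
                 NA_real_)
  tibble::tibble(
    locus = colnames(geno) %||% as.character(seq_len(ncol(geno))),
    freq = freq, n_called = n_called,
    monomorphic = is.na(freq) | freq <= 0 | freq >= 1
  )
}

#' Candidate parent pools per offspring spawn year
#'
#' For offspring first spawning in year `y`, candidate parents are fish with
#' a spawn event in years `y - a` for ages `a` in `allowed_age_gap`, across
#' all programs. In `constrained` mode candidate pairs must additionally
#' consist of two fish of opposite resolved sex with spawn events at the
#' same program on the same recorded date; in `unconstrained` mode any two
#' distinct pool adults form a candidate pair (sex is ignored for pairing).
#' Iteroparous fish appear in the pool of every year in which they spawned.
#'
#' @param events fish-level spawn events from [cluster_spawn_events()]
#'   (one row per event: `fish_id`, `program`, `spawn_date`, `spawn_year`,
#'   `resolved_sex`).
#' @param mode `"constrained"` or `"unconstrained"`.
#' @param config a [parentage_config()].
#' @return list keyed by offspring spawn year (character), each with
#'   `adults` (tibble `fish_id`, `resolved_sex`), `pairs` (constrained mode:
#'   tibble `fish_a`, `fish_b` of allowed pairs) and `n_pairs` (candidate
#'   pair count used for the pool-size adjustment).
#' @export
build_candidate_pools <- function(events, mode = c("constrained", "unconstrained"),
                                  config = parentage_config()) {
  mode <- match.arg(mode)
  gap <- config$allowed_age_gap
  years <- sort(unique(events$spawn_year))
  out <- list()
  for (y in years) {
    win <- (y - gap[2]):(y - gap[1])
    ev <- events[events$spawn_year %in% win, , drop = FALSE]
    if (nrow(ev) == 0) next
    adults <- dplyr::distinct(ev[, c("fish_id", "resolved_sex")])
    if (mode == "constrained") {
      prs <- dplyr::distinct(ev[, c("fish_id", "resolved_sex", "program", "spawn_date")])
      f <- prs[prs$resolved_sex == "F", ]
      m <- prs[prs$resolved_sex == "M", ]
      pairs <- dplyr::inner_join(
        f[, c("fish_id", "program", "spawn_date")],
        m[, c("fish_id", "program", "spawn_date")],
        by = c("program", "spawn_date"), suffix = c("_a", "_b"),
        relationship = "many-to-many")
      pairs <- dplyr::distinct(pairs[, c("fish_id_a", "fish_id_b")])
      names(pairs) <- c("fish_a", "fish_b")
      out[[as.character(y)]] <- list(adults = adults, pairs = pairs,
                                     n_pairs = nrow(pairs))
    } else {
      n <- nrow(adults)
      out[[as.character(y)]] <- list(adults = adults, pairs = NULL,
                                     n_pairs = n * (n - 1) / 2)
    }
  }
  out
}

# exact trio LODs for a batch of aligned (offspring, mother, father)
# genotype rows; returns lod, n_loci, n_incompatible per row
batch_trio_lod <- function(Go, Gm, Gf, tables) {
  L <- tables$n_loci
  P <- nrow(Gm)
  idx <- trio_index(Gm, Gf, Go)              # P x L, NA where any member missing
  idx[, tables$monomorphic] <- NA_integer_
  lmat <- matrix(rep(seq_len(L), each = P), P, L)
  flat <- lmat + (idx - 1L) * L
  v <- tables$lr_trio[flat]
  inc <- tables$incompat27[idx]
  ok <- !is.na(v)
  v[!ok] <- 0
  list(lod = rowSums(matrix(v, P, L)),
       n_loci = rowSums(matrix(ok, P, L)),
       n_incompatible = rowSums(matrix(inc & ok, P, L)))
}

#' Assign each offspring its most likely parent pair
#'
#' Candidate parents are prescreened per offspring by the exact
#' single-parent LOD (computed for the whole pool by a matrix product of
#' one-hot genotypes); full trio LODs are then evaluated for pairs among the
#' `top_k` prescreen candidates (in constrained mode, allowed pairs with at
#' least one prescreen member). The maximum-a-posteriori relationship over
#' the four hypotheses (parent pair, mother only, father only, unrelated;
#' equal priors) classifies the best pair; LOD ties break toward unrelated.
#' Mother/father roles in a pair follow resolved sex when available (the
#' trio likelihood is symmetric in the two parents).
#'
#' @param geno fish-level genotype matrix over the analysis loci (canonical
#'   sample genotypes; rownames = fish ids).
#' @param offspring tibble with `fish_id` and `spawn_year` (the fish's first
#'   spawn season).
#' @param pools output of [build_candidate_pools()] for the same mode.
#' @param tables [trio_tables()] built from the adult allele frequencies.
#' @param config a [parentage_config()].
#' @return tibble of trio assignments: `offspring_fish`, `mother_fish`,
#'   `father_fish`, `lod`, `map_category`, `n_loci`, `n_compatible`,
#'   `n_incompatible`, `pool_adults`, `pool_size`.
#' @export
assign_parentage <- function(geno, offspring, pools, tables,
                             config = parentage_config()) {
  res <- list()
  for (y in sort(unique(offspring$spawn_year))) {
    pool <- pools[[as.character(y)]]
    off_y <- offspring$fish_id[offspring$spawn_year == y]
    if (length(off_y) == 0) next
    off_prog <- if ("program" %in% names(offspring))
      offspring$program[offspring$spawn_year == y] else rep(NA_character_, length(off_y))
    if (is.null(pool) || nrow(pool$adults) < 2) {
      res[[length(res) + 1L]] <- tibble::tibble(
        offspring_fish = off_y, program = off_prog, mother_fish = NA_character_,
        father_fish = NA_character_, lod = NA_real_,
        map_category = "unassignable", n_loci = NA_integer_,
        n_compatible = NA_integer_, n_incompatible = NA_integer_,
        pool_adults = if (is.null(pool)) 0L else nrow(pool$adults),
        pool_size = 0, spawn_year = y)
      next
    }
    for (p in unique(off_prog)) {
      sel <- which(off_prog %in% p)
      a <- assign_pool(geno[off_y[sel], , drop = FALSE], off_y[sel], pool,
                       geno, tables_for(tables, p), config)
      a$offspring_fish <- off_y[sel]
      a$program <- p
      a$spawn_year <- y
      res[[length(res) + 1L]] <- a
    }
  }
  dplyr::bind_rows(res)
}

# tables may be one trio_tables (pooled frequencies) or a named list per
# program (per_program frequencies)
tables_for <- function(tables, program) {
  if (inherits(tables, "trio_tables")) return(tables)
  tbl <- if (!is.na(program)) tables[[program]] else NULL
  tbl %||% tables[[1]]
}

# Evaluate a batch of offspring genotypes against one candidate pool.
# Go: offspring genotype matrix; off_ids: fish ids to exclude from their own
# pool (NULL for simulated null offspring); geno: fish-level genotypes for
# the pool adults. Returns one row per offspring row of Go. Unconstrained
# pools (pool$pairs NULL) are evaluated fully vectorized: all pairs among
# the top-K prescreen candidates of all offspring go through one batched
# trio-LOD computation.
assign_pool <- function(Go, off_ids, pool, geno, tables, config) {
  adults <- pool$adults$fish_id
  adult_sex <- stats::setNames(pool$adults$resolved_sex, adults)
  Ga <- geno[adults, , drop = FALSE]
  LODs <- po_weight_matrix(Go, tables) %*% t(genotype_onehot(Ga))
  if (!is.null(off_ids)) {
    self <- cbind(seq_along(off_ids), match(off_ids, adults))
    LODs[self[!is.na(self[, 2]), , drop = FALSE]] <- -Inf
  }
  K <- min(config$top_k, length(adults))
  n <- nrow(Go)
  topidx <- t(apply(LODs, 1, function(r) order(r, decreasing = TRUE)[seq_len(K)]))
  if (K == 1) topidx <- matrix(topidx, n, 1)

  if (is.null(pool$pairs)) {
    pc <- utils::combn(K, 2L)                       # candidate pair template
    P <- ncol(pc)
    ia <- topidx[, pc[1, ], drop = FALSE]           # n x P adult indices
    ib <- topidx[, pc[2, ], drop = FALSE]
    lodm <- matrix(-Inf, n, P)
    nlm <- matrix(0L, n, P)
    nim <- matrix(0L, n, P)
    chunk <- max(1L, floor(8e6 / (P * tables_first(tables)$n_loci)))
    for (s in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
      rows <- rep(s, each = P)
      bt <- batch_trio_lod(Go[rows, , drop = FALSE],
                           Ga[as.vector(t(ia[s, , drop = FALSE])), , drop = FALSE],
                           Ga[as.vector(t(ib[s, , drop = FALSE])), , drop = FALSE],
                           tables)
      lodm[s, ] <- matrix(bt$lod, length(s), P, byrow = TRUE)
      nlm[s, ] <- matrix(bt$n_loci, length(s), P, byrow = TRUE)
      nim[s, ] <- matrix(bt$n_incompatible, length(s), P, byrow = TRUE)
    }
    lodm[nlm < config$min_loci_for_trio] <- -Inf
    b <- max.col(lodm, ties.method = "first")
    sel <- cbind(seq_len(n), b)
    pa_i <- ia[sel]; pb_i <- ib[sel]
    res <- tibble::tibble(
      offspring_fish = if (is.null(off_ids)) NA_character_ else off_ids,
      mother_fish = adults[pa_i], father_fish = adults[pb_i],
      lod = lodm[sel],
      lod_a = LODs[cbind(seq_len(n), pa_i)],
      lod_b = LODs[cbind(seq_len(n), pb_i)],
      n_loci = nlm[sel], n_incompatible = nim[sel])
  } else {
    pr <- pool$pairs
    res <- vector("list", n)
    for (i in seq_len(n)) {
      off <- if (is.null(off_ids)) NA_character_ else off_ids[i]
      top <- adults[topidx[i, ]]
      sel <- (pr$fish_a %in% top | pr$fish_b %in% top)
      if (!is.na(off)) sel <- sel & pr$fish_a != off & pr$fish_b != off
      cand <- as.matrix(pr[sel, c("fish_a", "fish_b")])
      if (nrow(cand) == 0) {
        res[[i]] <- tibble::tibble(
          offspring_fish = off, mother_fish = NA_character_,
          father_fish = NA_character_, lod = NA_real_, lod_a = NA_real_,
          lod_b = NA_real_, n_loci = NA_integer_, n_incompatible = NA_integer_)
        next
      }
      bt <- batch_trio_lod(Go[rep(i, nrow(cand)), , drop = FALSE],
                           geno[cand[, 1], , drop = FALSE],
                           geno[cand[, 2], , drop = FALSE], tables)
      bt$lod[bt$n_loci < config$min_loci_for_trio] <- -Inf
      j <- which.max(bt$lod)
      res[[i]] <- tibble::tibble(
        offspring_fish = off, mother_fish = cand[j, 1],
        father_fish = cand[j, 2], lod = bt$lod[j],
        lod_a = LODs[i, match(cand[j, 1], adults)],
        lod_b = LODs[i, match(cand[j, 2], adults)],
        n_loci = bt$n_loci[j], n_incompatible = bt$n_incompatible[j])
    }
    res <- dplyr::bind_rows(res)
  }

  # four-hypothesis MAP per offspring; ties break toward unrelated
  lod_pair <- res$lod
  best <- pmax(lod_pair, res$lod_a, res$lod_b, 0, na.rm = FALSE)
  cat0 <- ifelse(is.na(lod_pair), "unassignable",
          ifelse(best <= 0, "unrelated",
          ifelse(lod_pair == best, "parent_pair",
          ifelse(res$lod_a == best, "single_a", "single_b"))))
  # order each pair by resolved sex where available
  sxa <- unname(adult_sex[res$mother_fish])
  sxb <- unname(adult_sex[res$father_fish])
  swap <- !is.na(sxa) & !is.na(sxb) & sxa == "M" & sxb == "F"
  tmp <- res$mother_fish[swap]
  res$mother_fish[swap] <- res$father_fish[swap]
  res$father_fish[swap] <- tmp
  cat0[swap & cat0 == "single_a"] <- "single_b_swapped"
  cat0[swap & cat0 == "single_b"] <- "single_a"
  cat0[cat0 == "single_b_swapped"] <- "single_b"
  sxa2 <- unname(adult_sex[res$mother_fish])
  sxb2 <- unname(adult_sex[res$father_fish])
  res$map_category <- ifelse(cat0 == "single_a",
    ifelse(!is.na(sxa2) & sxa2 == "M", "father_only", "mother_only"),
    ifelse(cat0 == "single_b",
      ifelse(!is.na(sxb2) & sxb2 == "F", "mother_only", "father_only"),
      cat0))
  res$n_compatible <- res$n_loci - res$n_incompatible
  res$lod_a <- NULL
  res$lod_b <- NULL
  res$pool_adults <- length(adults)
  res$pool_size <- pool$n_pairs
  res$lod[is.infinite(res$lod)] <- NA_real_
  res$map_category[is.na(res$lod)] <- "unassignable"
  res
}

tables_first <- function(tables)
  if (inherits(tables, "trio_tables")) tables else tables[[1]]

# draw n unrelated observed genotype vectors from per-locus observed
# genotype marginals (n x 3 rows per locus) with per-locus missingness
draw_null_genotypes <- function(marg, missing_rates, n) {
  L <- nrow(marg)
  mr <- rep_len(missing_rates, L)
  c1 <- matrix(marg[, 1], n, L, byrow = TRUE)
  c2 <- matrix(marg[, 1] + marg[, 2], n, L, byrow = TRUE)
  u <- matrix(stats::runif(n * L), n, L)
  g <- (u > c1) + (u > c2)
  g[matrix(stats::runif(n * L), n, L) < matrix(mr, n, L, byrow = TRUE)] <- NA_integer_
  storage.mode(g) <- "integer"
  g
}

#' Monte-Carlo null distribution of the best-pair LOD per pool stratum
#'
#' For each offspring-year stratum and each program with offspring in that
#' year, simulates `null_sim_size` fully unrelated offspring — observed
#' genotypes drawn from the program's own allele frequencies passed through
#' the error model (so population structure among programs is reflected in
#' the null), with the empirical per-locus missingness — and evaluates each
#' against the stratum's real candidate pool through the same machinery as
#' real offspring. The result is the null distribution of the maximum pair
#' LOD over the pool for an unrelated offspring of that program and year.
#'
#' @param geno fish-level genotype matrix (the pool adults).
#' @param events fish-level spawn events (for per-program frequencies).
#' @param pools output of [build_candidate_pools()].
#' @param tables a [trio_tables()].
#' @param config a [parentage_config()].
#' @param seed integer seed.
#' @return nested list `[[year]][[program]]` of null best-LOD vectors.
#' @export
simulate_null_best_lods <- function(geno, events, pools, tables,
                                    config = parentage_config(), seed = 1L) {
  set.seed(seed)
  miss <- colMeans(is.na(geno))
  ev_ord <- events[order(events$spawn_year, events$spawn_date), , drop = FALSE]
  ev1 <- ev_ord[!duplicated(ev_ord$fish_id), , drop = FALSE]
  prog_of <- stats::setNames(ev1$program, ev1$fish_id)
  progs <- sort(unique(ev1$program))
  # null offspring genotypes are drawn from each program's own observed
  # marginals so that population structure is reflected in the null
  marg_by_prog <- lapply(stats::setNames(progs, progs), function(p) {
    tbl <- tables_for(tables, p)
    if (!inherits(tables, "trio_tables")) return(tbl$marg)
    ids <- ev1$fish_id[ev1$program == p]
    f <- estimate_allele_freqs(geno[ids, , drop = FALSE])$freq
    f[is.na(f)] <- 0.5
    h <- cbind((1 - f)^2, 2 * f * (1 - f), f^2)
    h %*% tbl$kernel
  })
  first_year <- tapply(events$spawn_year, events$fish_id, min)
  out <- list()
  for (y in names(pools)) {
    pool <- pools[[y]]
    if (nrow(pool$adults) < 2) next
    off_prog <- unique(prog_of[names(first_year)[first_year == as.integer(y)]])
    off_prog <- off_prog[!is.na(off_prog)]
    if (length(off_prog) == 0) off_prog <- progs
    out[[y]] <- lapply(stats::setNames(off_prog, off_prog), function(p) {
      Gn <- draw_null_genotypes(marg_by_prog[[p]], miss, config$null_sim_size)
      a <- assign_pool(Gn, NULL, pool, geno, tables_for(tables, p), config)
      ifelse(is.na(a$lod), -Inf, a$lod)
    })
  }
  out
}

#' Attach Monte-Carlo FDR q-values to trio assignments
#'
#' For each offspring, the exceedance probability of its best pair LOD is
#' estimated against the null distribution of the best-pair LOD over its
#' own candidate pool (from [simulate_null_best_lods()]; this is the
#' Monte-Carlo probability that a fully unrelated offspring would score as
#' high against the same pool, so the pool size is accounted for by
#' construction). P-values are converted to q-values by Benjamini-Hochberg
#' across offspring; assignments are accepted when the MAP category is
#' `parent_pair` and `q <= fdr_threshold`.
#'
#' @param assignments tibble from [assign_parentage()].
#' @param null_best named per-year list from [simulate_null_best_lods()].
#' @param config a [parentage_config()].
#' @return assignments with `p_value`, `q`, `accepted`.
#' @export
estimate_fdr <- function(assignments, null_best, config = parentage_config()) {
  if (config$null_sim_size < 1 / config$fdr_threshold)
    warning(sprintf("null simulation size %d gives p resolution %.3g, coarser than fdr_threshold",
                    config$null_sim_size, 1 / config$null_sim_size))
  p <- vapply(seq_len(nrow(assignments)), function(i) {
    yr <- null_best[[as.character(assignments$spawn_year[i])]]
    if (is.na(assignments$lod[i]) || is.null(yr)) return(1)
    pg <- assignments$program[i]
    nb <- if (!is.na(pg) && !is.null(yr[[pg]])) yr[[pg]] else unlist(yr)
    mean(nb >= assignments$lod[i])
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  out <- assignments
  out$p_value <- p
  out$q <- q
  out$accepted <- out$map_category == "parent_pair" & out$q <= config$fdr_threshold
  out
}

#' Reconcile constrained and unconstrained parentage runs
#'
#' Accepted trios (MAP parent pair, q below threshold) from the two runs are
#' merged per offspring: identical pairs in both runs are kept
#' (`both_runs`); trios accepted only in the unconstrained run are kept and
#' tagged as presumed metadata errors (`unconstrained_only`); when both runs
#' accept different pairs the lower-q trio is kept, ties toward the
#' constrained run (`constrained_preferred`, logged); trios accepted only in
#' the constrained run are kept (`constrained_only`).
#'
#' @param constrained,unconstrained assignment tibbles from
#'   [estimate_fdr()].
#' @return list with `pedigree` (accepted trios + `provenance`, `q`) and
#'   `conflicts` (the case-3 log).
#' @export
reconcile_runs <- function(constrained, unconstrained) {
  ca <- constrained[constrained$accepted, , drop = FALSE]
  ua <- unconstrained[unconstrained$accepted, , drop = FALSE]
  pair_key <- function(df)
    paste(pmin(df$mother_fish, df$father_fish),
          pmax(df$mother_fish, df$father_fish))
  ca$key <- pair_key(ca); ua$key <- pair_key(ua)
  offs <- union(ca$offspring_fish, ua$offspring_fish)
  ci <- match(offs, ca$offspring_fish)
  ui <- match(offs, ua$offspring_fish)
  rows <- list(); conf <- list()
  for (k in seq_along(offs)) {
    cc <- if (!is.na(ci[k])) ca[ci[k], ] else NULL
    uu <- if (!is.na(ui[k])) ua[ui[k], ] else NULL
    if (!is.null(cc) && !is.null(uu)) {
      if (cc$key == uu$key) {
        r <- cc; r$provenance <- "both_runs"
      } else if (uu$q < cc$q) {
        r <- uu; r$provenance <- "constrained_preferred"
        conf[[length(conf) + 1L]] <- tibble::tibble(
          offspring_fish = offs[k], kept = "unconstrained",
          q_constrained = cc$q, q_unconstrained = uu$q)
      } else {
        r <- cc; r$provenance <- "constrained_preferred"
        conf[[length(conf) + 1L]] <- tibble::tibble(
          offspring_fish = offs[k], kept = "constrained",
          q_constrained = cc$q, q_unconstrained = uu$q)
      }
    } else if (!is.null(uu)) {
      r <- uu; r$provenance <- "unconstrained_only"
    } else {
      r <- cc; r$provenance <- "constrained_only"
    }
    rows[[length(rows) + 1L]] <- r
  }
  ped <- dplyr::bind_rows(rows)
  ped$key <- NULL
  list(pedigree = ped,
       conflicts = if (length(conf)) dplyr::bind_rows(conf) else
         tibble::tibble(offspring_fish = character(), kept = character(),
                        q_constrained = numeric(), q_unconstrained = numeric()))
}

#' Remove improbable trios from a reconciled pedigree
#'
#' Drops trios where both parents share the same resolved sex
#' (`sex_conflict`), where a parent has no spawn event at least
#' `min(allowed_age_gap)` years before the offspring's first event
#' (`date_conflict`), or where a parent is the offspring itself
#' (`self_parent`).
#'
#' @param pedigree tibble from [reconcile_runs()].
#' @param events fish-level spawn events (for spawn years).
#' @param sex_of named character vector fish_id -> resolved sex.
#' @param config a [parentage_config()].
#' @return list with `pedigree` (retained) and `removals` (with `reason`).
#' @export
remove_improbable_trios <- function(pedigree, events, sex_of,
                                    config = parentage_config()) {
  if (nrow(pedigree) == 0)
    return(list(pedigree = pedigree,
                removals = tibble::tibble(offspring_fish = character(),
                                          reason = character())))
  min_gap <- config$allowed_age_gap[1]
  first_year <- tapply(events$spawn_year, events$fish_id, min)
  reason <- rep(NA_character_, nrow(pedigree))
  same_sex <- !is.na(sex_of[pedigree$mother_fish]) &
    !is.na(sex_of[pedigree$father_fish]) &
    sex_of[pedigree$mother_fish] == sex_of[pedigree$father_fish]
  self <- pedigree$mother_fish == pedigree$offspring_fish |
    pedigree$father_fish == pedigree$offspring_fish
  off_y <- first_year[pedigree$offspring_fish]
  late <- first_year[pedigree$mother_fish] > off_y - min_gap |
    first_year[pedigree$father_fish] > off_y - min_gap
  reason[late] <- "date_conflict"
  reason[same_sex] <- "sex_conflict"
  reason[self] <- "self_parent"
  keep <- is.na(reason)
  list(pedigree = pedigree[keep, , drop = FALSE],
       removals = tibble::tibble(
         offspring_fish = pedigree$offspring_fish[!keep],
         reason = reason[!keep]))
}

#' Run one full parentage pass
#'
#' Convenience orchestration: offspring definition (every fish, by first
#' spawn season), pool construction, allele-frequency estimation, trio
#' tables, assignment, null simulation and FDR.
#'
#' @param geno fish-level genotype matrix over analysis loci.
#' @param events fish-level spawn events.
#' @param mode `"constrained"` or `"unconstrained"`.
#' @param config a [parentage_config()].
#' @param seed seed for the null simulation.
#' @param tables optionally precomputed [trio_tables()].
#' @param null_best optionally precomputed [simulate_null_best_lods()]
#'   output.
#' @return list with `assignments`, `tables`, `null_best`.
#' @export
run_parentage <- function(geno, events, mode, config = parentage_config(),
                          seed = 1L, tables = NULL, null_best = NULL) {
  ev_ord <- events[order(events$spawn_year, events$spawn_date), , drop = FALSE]
  ev1 <- ev_ord[!duplicated(ev_ord$fish_id), , drop = FALSE]
  offspring <- tibble::tibble(fish_id = ev1$fish_id,
                              spawn_year = ev1$spawn_year,
                              program = ev1$program)
  pools <- build_candidate_pools(events, mode, config)
  if (is.null(tables)) {
    if (config$allele_freq_source == "per_program") {
      progs <- sort(unique(ev1$program))
      tables <- lapply(stats::setNames(progs, progs), function(p) {
        ids <- ev1$fish_id[ev1$program == p]
        f <- estimate_allele_freqs(geno[ids, , drop = FALSE])$freq
        f[is.na(f)] <- 0.5
        trio_tables(f, config$epsilon)
      })
    } else {
      af <- estimate_allele_freqs(geno)
      tables <- trio_tables(af$freq, config$epsilon)
    }
  }
  if (is.null(null_best)) {
    null_best <- simulate_null_best_lods(geno, events, pools, tables, config,
                                         seed = child_seed(seed, paste0("null_", mode)))
  }
  asg <- assign_parentage(geno, offspring, pools, tables, config)
  asg <- estimate_fdr(asg, null_best, config)
  list(assignments = asg, tables = tables, null_best = null_best)
}
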