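#' Default hatchery program layout
#'
#' Four programs in two genetic lineages: three programs of one lineage (two
#' large, spawning each female with a single male, and one small, dividing
#' each female's eggs between two males) and one program founded from a
#' second, divergent lineage (small, two males per female).
#'
#' @param spawners_per_year spawners per program per year (recycled).
#' @return tibble with `program`, `lineage`, `spawners_per_year`,
#'   `mating_rule`.
#' @export
default_programs <- function(spawners_per_year = 200L) {
  tibble::tibble(
    program = c("P1", "P2", "P3", "P4"),
    lineage = c("L1", "L1", "L1", "L2"),
    spawners_per_year = rep_len(as.integer(spawners_per_year), 4),
    mating_rule = c("one_male", "one_male", "two_males", "two_males")
  )
}

default_age_dist <- function() {
  list(
    L1 = list(F = c(0.65, 0.30, 0.04, 0.009, 0.001),
              M = c(0.80, 0.18, 0.015, 0.004, 0.001)),
    L2 = list(F = c(0.12, 0.80, 0.06, 0.015, 0.005),
              M = c(0.20, 0.72, 0.06, 0.015, 0.005))
  )
}

#' Build a validated simulation configuration
#'
#' Parameters describe a multi-program hatchery broodstock system: founder
#' allele frequencies and lineage divergence, per-program spawner numbers and
#' mating rules, age-at-return distributions, iteroparity and within-season
#' repeat-spawning probabilities (per lineage and sex), straying, an
#' inversion-indicator locus with an age-at-return effect, family-size
#' overdispersion, per-gene-copy genotyping error, missing data, and rare
#' metadata errors.
#'
#' @param n_loci number of autosomal analysis loci.
#' @param founder_freq_range interval in (0,1) for ancestral frequencies.
#' @param lineage_fst Balding-Nichols divergence between the two lineages.
#' @param programs tibble as produced by [default_programs()].
#' @param years consecutive calendar spawn-season labels.
#' @param age_at_return_dist per lineage and sex, probabilities over ages 2-6.
#' @param iteroparity_prob,repeat_spawn_prob per lineage and sex.
#' @param stray_matrix row-stochastic program x program return matrix;
#'   default 0.99 natal return, strays spread evenly.
#' @param omy05_freq_R per-lineage frequency of the rearranged allele.
#' @param omy05_age_effect per-lineage odds multiplier on age-2 return per R
#'   allele.
#' @param offspring_per_pair_mean,offspring_per_pair_dispersion negative
#'   binomial returning-offspring counts per mating.
#' @param epsilon_sim per-gene-copy genotyping error rate.
#' @param missing_rate per-call missing probability.
#' @param meta_error_sex_rate,meta_error_date_rate metadata error rates.
#' @param phenotypic_sex_unknown_rate rate of unrecorded phenotypic sex.
#' @param seed master integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_loci = 92L,
                       founder_freq_range = c(0.2, 0.8),
                       lineage_fst = 0.1,
                       programs = default_programs(),
                       years = 2011:2019,
                       age_at_return_dist = default_age_dist(),
                       iteroparity_prob = list(L1 = c(F = 0.12, M = 0.02),
                                               L2 = c(F = 0.002, M = 0.002)),
                       repeat_spawn_prob = list(L1 = c(F = 0.03, M = 0.20),
                                                L2 = c(F = 0.01, M = 0.20)),
                       stray_matrix = NULL,
                       omy05_freq_R = c(L1 = 0.15, L2 = 0.20),
                       omy05_age_effect = c(L1 = 1.0, L2 = 1.5),
                       offspring_per_pair_mean = 1.0,
                       offspring_per_pair_dispersion = 0.5,
                       epsilon_sim = 0.005,
                       missing_rate = 0.03,
                       meta_error_sex_rate = 0.002,
                       meta_error_date_rate = 0.002,
                       phenotypic_sex_unknown_rate = 0.01,
                       seed = 1L) {
  np <- nrow(programs)
  if (is.null(stray_matrix)) {
    stray_matrix <- matrix(0.01 / (np - 1), np, np)
    diag(stray_matrix) <- 0.99
  }
  stopifnot(nrow(stray_matrix) == np, ncol(stray_matrix) == np)
  dimnames(stray_matrix) <- list(programs$program, programs$program)
  cfg <- list(n_loci = as.integer(n_loci),
              founder_freq_range = founder_freq_range,
              lineage_fst = lineage_fst, programs = programs,
              years = as.integer(years),
              age_at_return_dist = age_at_return_dist,
              iteroparity_prob = iteroparity_prob,
              repeat_spawn_prob = repeat_spawn_prob,
              stray_matrix = stray_matrix,
              omy05_freq_R = omy05_freq_R,
              omy05_age_effect = omy05_age_effect,
              offspring_per_pair_mean = offspring_per_pair_mean,
              offspring_per_pair_dispersion = offspring_per_pair_dispersion,
              epsilon_sim = epsilon_sim, missing_rate = missing_rate,
              meta_error_sex_rate = meta_error_sex_rate,
              meta_error_date_rate = meta_error_date_rate,
              phenotypic_sex_unknown_rate = phenotypic_sex_unknown_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_loci >= 1,
            all(cfg$founder_freq_range > 0), all(cfg$founder_freq_range < 1),
            cfg$founder_freq_range[1] <= cfg$founder_freq_range[2],
            cfg$epsilon_sim >= 0, cfg$epsilon_sim < 0.5,
            cfg$missing_rate >= 0, cfg$missing_rate <= 1,
            all(diff(cfg$years) == 1))
  if (cfg$lineage_fst < 0 || cfg$lineage_fst >= 1)
    stop("lineage_fst must lie in [0, 1)")
  for (lin in names(cfg$age_at_return_dist)) for (sx in c("F", "M")) {
    pv <- cfg$age_at_return_dist[[lin]][[sx]]
    if (abs(sum(pv) - 1) > 1e-9)
      stop("age_at_return_dist[", lin, "][", sx, "] does not sum to 1")
  }
  if (any(abs(rowSums(cfg$stray_matrix) - 1) > 1e-9))
    stop("stray_matrix rows must sum to 1")
  invisible(cfg)
}

#' Locus panel of a simulated dataset
#'
#' Autosomal analysis loci plus a Y-linked sex marker and an
#' inversion-indicator locus, with their role tags.
#'
#' @param cfg a [sim_config()].
#' @return tibble with `locus`, `role`, `typed_all_years`.
#' @export
sim_locus_panel <- function(cfg) {
  tibble::tibble(
    locus = c(sprintf("L%03d", seq_len(cfg$n_loci)), "SexY", "Omy05inv"),
    role = c(rep("autosomal_analysis", cfg$n_loci), "sex_marker", "omy05_marker"),
    typed_all_years = TRUE
  )
}

#' Draw per-lineage founder allele frequencies
#'
#' Ancestral frequencies are uniform over `founder_freq_range`; each lineage
#' then draws locus frequencies from the Balding-Nichols beta distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral value, giving expected
#' divergence `F = lineage_fst` between lineages. `lineage_fst = 0` yields
#' identical vectors.
#'
#' @param cfg a [sim_config()].
#' @return list with `ancestral` and one frequency vector per lineage
#'   (autosomal loci, plus the lineage's inversion allele frequency appended
#'   under the inversion locus name).
#' @export
draw_founder_frequencies <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(child_seed(cfg$seed, "founder_freqs"))
  p0 <- stats::runif(cfg$n_loci, cfg$founder_freq_range[1], cfg$founder_freq_range[2])
  lineages <- unique(cfg$programs$lineage)
  F <- cfg$lineage_fst
  out <- lapply(lineages, function(lin) {
    p <- if (F == 0) p0 else
      stats::rbeta(cfg$n_loci, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
    # keep loci polymorphic: beta draws can hit the boundary numerically
    p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
    names(p) <- sprintf("L%03d", seq_len(cfg$n_loci))
    c(p, Omy05inv = unname(cfg$omy05_freq_R[lin]))
  })
  names(out) <- lineages
  c(list(ancestral = p0), out)
}

# age-2 odds reweighting by inversion genotype: g_R copies of R multiply the
# odds of returning at age 2 by effect^g_R
age_probs_omy05 <- function(base, effect, g_R) {
  if (effect == 1 || g_R == 0) return(base)
  k <- effect^g_R
  p2 <- base[1] * k / (base[1] * k + (1 - base[1]))
  c(p2, base[-1] * (1 - p2) / (1 - base[1]))
}

season_dates <- function(year) {
  seq(as.Date(sprintf("%d-12-01", year - 1L)), as.Date(sprintf("%d-02-28", year)),
      by = "day")
}

#' Forward simulation of multi-program broodstock pedigrees
#'
#' Simulates spawner pools year by year. Each year a program's pool consists
#' of returning offspring of earlier matings (age at return drawn per
#' lineage, sex and inversion genotype; return program per the stray matrix)
#' and scheduled iteroparous returners, topped up to the program size with
#' new founders drawn from the lineage gene pool. Spawning is organized on
#' discrete days within a December-February season; each female is mated with
#' one or two males present on her day (per the program's mating rule), each
#' mating contributes a negative-binomial number of returning offspring, and
#' fish may spawn again within the season (repeat spawners) or in a later
#' year (iteroparous).
#'
#' @param cfg a [sim_config()].
#' @return a `truth_bundle` list: `config`, `panel`, `allele_freqs`, `fish`
#'   (one row per physical fish), `events` (one row per spawn event),
#'   `true_pedigree` (offspring, mother, father, mating year/program), and
#'   `genotypes` (true diploid calls, fish x locus).
#' @export
simulate_population <- function(cfg) {
  validate_sim_config(cfg)
  freqs <- draw_founder_frequencies(cfg)
  set.seed(child_seed(cfg$seed, "forward"))
  panel <- sim_locus_panel(cfg)
  L <- nrow(panel)
  auto <- seq_len(cfg$n_loci)
  i_sex <- cfg$n_loci + 1L
  i_omy <- cfg$n_loci + 2L
  progs <- cfg$programs

  geno_chunks <- list()
  fish_rows <- list()
  ped_rows <- list()
  event_rows <- list()
  n_fish <- 0L
  # recruits / iteroparous returns keyed by "program|year"
  queue <- new.env(parent = emptyenv())
  push <- function(key, ids) assign(key, c(queue[[key]] %||% integer(), ids), envir = queue)

  new_fish <- function(n, lineage, program, birth_year, sex = NULL, geno = NULL) {
    if (n == 0L) return(integer())
    ids <- n_fish + seq_len(n)
    n_fish <<- n_fish + n
    if (is.null(sex)) sex <- sample(c("F", "M"), n, replace = TRUE)
    if (is.null(geno)) {
      p <- freqs[[lineage]]
      g <- matrix(stats::rbinom(n * cfg$n_loci, 2L, rep(p[auto], each = n)), n, cfg$n_loci)
      gs <- ifelse(sex == "M", 1L, 0L)
      go <- stats::rbinom(n, 2L, p[["Omy05inv"]])
      geno <- cbind(g, gs, go)
    }
    geno_chunks[[length(geno_chunks) + 1L]] <<- geno
    fish_rows[[length(fish_rows) + 1L]] <<- tibble::tibble(
      fish = ids, sex = sex, natal_program = program, lineage = lineage,
      birth_year = birth_year, founder = is.null(birth_year) || all(is.na(birth_year)))
    ids
  }

  fish_sex <- character(0)     # grows with fish; duplicated from fish_rows for speed
  fish_omy <- integer(0)
  track <- function(ids) {
    fr <- fish_rows[[length(fish_rows)]]
    fish_sex[fr$fish] <<- fr$sex
    gg <- geno_chunks[[length(geno_chunks)]]
    fish_omy[fr$fish] <<- gg[, i_omy]
  }

  draw_age <- function(lineage, sex, g_R) {
    pv <- age_probs_omy05(cfg$age_at_return_dist[[lineage]][[sex]],
                          cfg$omy05_age_effect[[lineage]], g_R)
    sample(2:6, 1L, prob = pv)
  }

  for (y in cfg$years) {
    dates <- season_dates(y)
    spawn_days <- sort(sample(dates, 12L))
    for (k in seq_len(nrow(progs))) {
      pr <- progs$program[k]
      lin <- progs$lineage[k]
      key <- paste0(pr, "|", y)
      pool <- unique(queue[[key]] %||% integer())
      need <- progs$spawners_per_year[k] - length(pool)
      if (need > 0) {
        fd <- new_fish(need, lin, pr, birth_year = NA_integer_)
        track(fd)
        pool <- c(pool, fd)
      }
      sexes <- fish_sex[pool]
      if (!any(sexes == "M") || !any(sexes == "F")) {
        warning(sprintf("no complete spawner pool at %s in %d; year skipped", pr, y))
        next
      }
      day1 <- sample(spawn_days, length(pool), replace = TRUE)
      rep_p <- vapply(seq_along(pool), function(i)
        cfg$repeat_spawn_prob[[lin]][[sexes[i]]], numeric(1))
      rep_mask <- stats::runif(length(pool)) < rep_p
      ev <- tibble::tibble(fish = pool, sex = sexes, date = day1)
      if (any(rep_mask)) {
        d2 <- vapply(which(rep_mask), function(i) {
          cand <- spawn_days[spawn_days != day1[i]]
          sample(cand, 1L)
        }, spawn_days[1])
        ev <- dplyr::bind_rows(ev, tibble::tibble(
          fish = pool[rep_mask], sex = sexes[rep_mask], date = as.Date(d2)))
      }
      # mating: females paired with males sharing their spawn day
      male_ev <- ev[ev$sex == "M", ]
      fem_ev <- ev[ev$sex == "F", ]
      male_days <- unique(male_ev$date)
      # females on male-free days are moved to the nearest day with males
      off_day <- !(fem_ev$date %in% male_days)
      if (any(off_day)) {
        fem_ev$date[off_day] <- vapply(fem_ev$date[off_day], function(d)
          male_days[which.min(abs(as.numeric(male_days - d)))], male_days[1])
        fem_ev$date <- as.Date(fem_ev$date, origin = "1970-01-01")
      }
      ev <- dplyr::bind_rows(fem_ev, male_ev)
      n_mates <- if (progs$mating_rule[k] == "two_males") 2L else 1L
      matings_m <- integer(0); matings_f <- integer(0); matings_d <- as.Date(character(0))
      for (d in as.list(unique(fem_ev$date))) {
        fs <- fem_ev$fish[fem_ev$date == d]
        ms <- male_ev$fish[male_ev$date == d]
        for (f in fs) {
          mates <- if (length(ms) >= n_mates) sample(rep(ms, 2L), n_mates) else ms
          mates <- unique(mates)
          matings_f <- c(matings_f, rep(f, length(mates)))
          matings_m <- c(matings_m, mates)
          matings_d <- c(matings_d, rep(d, length(mates)))
        }
      }
      event_rows[[length(event_rows) + 1L]] <- tibble::tibble(
        fish = ev$fish, program = pr, spawn_year = y, spawn_date = ev$date)

      # returning offspring of this year's matings
      if (length(matings_f)) {
        mates_per_f <- table(matings_f)
        mu <- cfg$offspring_per_pair_mean / as.numeric(mates_per_f[as.character(matings_f)])
        n_off_pair <- stats::rnbinom(length(matings_f),
                                     size = cfg$offspring_per_pair_dispersion, mu = mu)
        tot <- sum(n_off_pair)
        if (tot > 0) {
          mo <- rep(matings_f, n_off_pair)
          fa <- rep(matings_m, n_off_pair)
          G <- do.call(rbind, geno_chunks)   # fish x L so far (ids are row order)
          Gm <- G[mo, , drop = FALSE]
          Gf <- G[fa, , drop = FALSE]
          ch <- (matrix(stats::runif(tot * L), tot, L) < Gm / 2) +
                (matrix(stats::runif(tot * L), tot, L) < Gf / 2)
          storage.mode(ch) <- "integer"
          sex_o <- ifelse(ch[, i_sex] == 1L, "M", "F")
          ch[, i_sex] <- ifelse(sex_o == "M", 1L, 0L)  # guard: YY impossible
          ids <- new_fish(tot, lin, pr, birth_year = rep(y, tot), sex = sex_o, geno = ch)
          track(ids)
          ped_rows[[length(ped_rows) + 1L]] <- tibble::tibble(
            offspring = ids, mother = mo, father = fa,
            mating_year = y, mating_program = pr)
          ages <- vapply(seq_len(tot), function(i)
            draw_age(lin, sex_o[i], ch[i, i_omy]), integer(1))
          ret_prog <- sample(progs$program, tot, replace = TRUE,
                             prob = cfg$stray_matrix[pr, ])
          ret_year <- y + ages
          keep <- ret_year <= max(cfg$years)
          for (i in which(keep))
            push(paste0(ret_prog[i], "|", ret_year[i]), ids[i])
        }
      }

      # iteroparous returns in a later year
      it_p <- vapply(seq_along(pool), function(i)
        cfg$iteroparity_prob[[lin]][[sexes[i]]], numeric(1))
      it_mask <- stats::runif(length(pool)) < it_p
      if (any(it_mask)) {
        gaps <- sample(1:2, sum(it_mask), replace = TRUE, prob = c(0.8, 0.2))
        ret_y <- y + gaps
        ret_p <- sample(progs$program, sum(it_mask), replace = TRUE,
                        prob = cfg$stray_matrix[pr, ])
        ok <- ret_y <= max(cfg$years)
        ids <- pool[it_mask][ok]
        for (i in seq_along(ids))
          push(paste0(ret_p[ok][i], "|", ret_y[ok][i]), ids[i])
      }
    }
  }

  G <- do.call(rbind, geno_chunks)
  colnames(G) <- panel$locus
  fish <- dplyr::bind_rows(fish_rows)
  rownames(G) <- sprintf("F%05d", fish$fish)
  fish$fish_id <- sprintf("F%05d", fish$fish)
  events <- dplyr::bind_rows(event_rows)
  events$fish_id <- sprintf("F%05d", events$fish)
  ped <- if (length(ped_rows)) dplyr::bind_rows(ped_rows) else
    tibble::tibble(offspring = integer(), mother = integer(), father = integer(),
                   mating_year = integer(), mating_program = character())
  ped$offspring_fish <- sprintf("F%05d", ped$offspring)
  ped$mother_fish <- sprintf("F%05d", ped$mother)
  ped$father_fish <- sprintf("F%05d", ped$father)

  structure(list(config = cfg, panel = panel, allele_freqs = freqs,
                 fish = fish, events = events,
                 true_pedigree = ped, genotypes = G),
            class = "truth_bundle")
}

#' Observe a simulated population: genotyping and metadata error
#'
#' Produces one sample per spawn event with a fresh sample ID. Each gene copy
#' of the true genotype is flipped independently with probability
#' `epsilon_sim`; each locus call is set missing with probability
#' `missing_rate`. Phenotypic sex is mislabeled at `meta_error_sex_rate` and
#' unrecorded at `phenotypic_sex_unknown_rate`; the recorded spawn date is
#' replaced by a different in-season date at `meta_error_date_rate`. The
#' Y-linked sex marker always reflects the true sex (subject only to
#' genotyping error and missingness). Fork length is drawn from an
#' age-dependent normal.
#'
#' @param truth a `truth_bundle` from [simulate_population()].
#' @param cfg the same [sim_config()].
#' @return list with `samples` (metadata tibble), `genotypes` (observed
#'   sample x locus matrix, 0/1/2/NA), `panel`, and `identity_map`
#'   (sample_id to fish_id).
#' @export
observe_population <- function(truth, cfg = truth$config) {
  set.seed(child_seed(cfg$seed, "observe"))
  ev <- truth$events[order(truth$events$spawn_year, truth$events$program,
                           truth$events$spawn_date, truth$events$fish), ]
  n <- nrow(ev)
  sample_id <- sprintf("S%06d", seq_len(n))
  Gt <- truth$genotypes[ev$fish, , drop = FALSE]
  L <- ncol(Gt)
  e <- cfg$epsilon_sim
  # per-copy flips: alt copies retained Binom(g, 1-e), ref copies flipped in
  Gobs <- matrix(stats::rbinom(n * L, as.vector(Gt), 1 - e) +
                 stats::rbinom(n * L, 2L - as.vector(Gt), e), n, L,
                 dimnames = list(sample_id, colnames(Gt)))
  Gobs[matrix(stats::runif(n * L) < cfg$missing_rate, n, L)] <- NA_integer_

  fish_tab <- truth$fish
  true_sex <- fish_tab$sex[match(ev$fish, fish_tab$fish)]
  phen <- true_sex
  flip <- stats::runif(n) < cfg$meta_error_sex_rate
  phen[flip] <- ifelse(true_sex[flip] == "F", "M", "F")
  phen[stats::runif(n) < cfg$phenotypic_sex_unknown_rate] <- "unknown"

  date_rec <- ev$spawn_date
  bad_date <- which(stats::runif(n) < cfg$meta_error_date_rate)
  if (length(bad_date)) {
    date_rec[bad_date] <- as.Date(vapply(bad_date, function(i) {
      dts <- season_dates(ev$spawn_year[i])
      sample(dts[dts != ev$spawn_date[i]], 1L)
    }, ev$spawn_date[1]), origin = "1970-01-01")
  }

  birth <- fish_tab$birth_year[match(ev$fish, fish_tab$fish)]
  age <- ifelse(is.na(birth), sample(2:4, n, replace = TRUE), ev$spawn_year - birth)
  length_mm <- round(stats::rnorm(n, 480 + 60 * age, 40))

  samples <- tibble::tibble(
    sample_id = sample_id,
    program = ev$program,
    spawn_date = date_rec,
    phenotypic_sex = phen,
    length_mm = length_mm,
    adipose_present = FALSE
  )
  list(samples = samples, genotypes = Gobs, panel = truth$panel,
       identity_map = tibble::tibble(sample_id = sample_id,
                                     fish_id = ev$fish_id))
}
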