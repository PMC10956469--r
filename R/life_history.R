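#' Classify spawning use per fish
#'
#' From the spawn events of each individual cluster: `once` (a single
#' event), `repeat` (two or more events within one spawn season),
#' `iteroparous` (events in two or more seasons), or
#' `repeat_and_iteroparous` (both). In use-exclusive summary tables the
#' combined label is counted as iteroparous.
#'
#' @param events fish-level spawn events from [cluster_spawn_events()].
#' @return tibble with one row per fish: `fish_id`, `use`, `n_events`,
#'   `n_years`, `sex`, `programs`, `cross_program`.
#' @export
classify_spawn_use <- function(events) {
  g <- dplyr::group_by(events, .data$fish_id)
  rec <- dplyr::summarise(
    g,
    n_events = dplyr::n(),
    n_years = dplyr::n_distinct(.data$spawn_year),
    repeat_within = any(table(.data$spawn_year) >= 2),
    sex = .data$resolved_sex[1],
    programs = list(unique(.data$program)),
    cross_program = dplyr::n_distinct(.data$program) > 1,
    .groups = "drop")
  rec$use <- with(rec, ifelse(
    n_events == 1, "once",
    ifelse(n_years >= 2 & repeat_within, "repeat_and_iteroparous",
           ifelse(n_years >= 2, "iteroparous", "repeat"))))
  rec$repeat_within <- NULL
  rec
}

#' Program x sex x use count table with percentages
#'
#' Fish are counted once per program at which they spawned (cross-program
#' fish appear in each program's column); the combined
#' repeat-and-iteroparous label maps to iteroparous, making the table
#' use-exclusive. Percentages use the program (or sex-within-program) totals
#' as denominators.
#'
#' @param use_records tibble from [classify_spawn_use()].
#' @return tibble with `program`, `sex` (`Total`/`F`/`M`), `use`, `n`, `pct`.
#' @export
spawn_use_table <- function(use_records) {
  long <- tidyr::unnest(use_records, "programs")
  long <- dplyr::rename(long, program = "programs")
  long$use_excl <- ifelse(long$use == "repeat_and_iteroparous", "iteroparous",
                          long$use)
  both <- dplyr::bind_rows(
    dplyr::mutate(long, sex_grp = "Total"),
    dplyr::mutate(long, sex_grp = .data$sex))
  cnt <- dplyr::count(both, .data$program, .data$sex_grp, .data$use_excl,
                      name = "n")
  cnt <- tidyr::complete(cnt, .data$program, .data$sex_grp,
                         use_excl = c("once", "iteroparous", "repeat"),
                         fill = list(n = 0L))
  cnt <- dplyr::group_by(cnt, .data$program, .data$sex_grp)
  cnt <- dplyr::mutate(cnt, pct = 100 * .data$n / sum(.data$n))
  out <- dplyr::ungroup(cnt)
  dplyr::rename(out, sex = "sex_grp", use = "use_excl")
}

#' Percent-of-use shares from a count table
#'
#' Pure arithmetic on use-exclusive counts: each use's percentage of the
#' per-program total, matching how the published use tables derive their
#' percentages from counts.
#'
#' @param counts tibble with `program`, `use`, `n`.
#' @return `counts` with a `pct` column.
#' @export
use_percentages <- function(counts) {
  g <- dplyr::group_by(counts, .data$program)
  dplyr::ungroup(dplyr::mutate(g, pct = 100 * .data$n / sum(.data$n)))
}

# most recent spawn year shared by both parents within the allowed age gap
# of the offspring's first spawn year
mating_years <- function(pedigree, events, allowed_age_gap = c(2L, 6L)) {
  yr_of <- split(events$spawn_year, events$fish_id)
  first_year <- vapply(yr_of, min, numeric(1))
  vapply(seq_len(nrow(pedigree)), function(i) {
    oy <- first_year[[pedigree$offspring_fish[i]]]
    shared <- intersect(yr_of[[pedigree$mother_fish[i]]],
                        yr_of[[pedigree$father_fish[i]]])
    shared <- shared[shared >= oy - allowed_age_gap[2] &
                     shared <= oy - allowed_age_gap[1]]
    if (length(shared) == 0) NA_real_ else max(shared)
  }, numeric(1))
}

#' Age records and age distributions from a pedigree
#'
#' Offspring age is the offspring's first spawn season minus the parents'
#' mating season (the most recent season both parents spawned within the
#' allowed age gap). Returns per-trio age records plus count/percentage
#' tables by program x age, program x sex x age, cohort year and return
#' year, and a size-at-age table where lengths are available. Return years
#' within the minimum age of the first sampled season are flagged censored
#' (their youngest possible parents predate sampling).
#'
#' @param pedigree accepted trios.
#' @param events fish-level spawn events (with `length_mm` if available).
#' @param allowed_age_gap inclusive age range.
#' @return list with `records`, `by_program_age`, `by_program_sex_age`,
#'   `by_cohort`, `by_return`, `size_at_age`, `censored_return_years`.
#' @export
tabulate_ages <- function(pedigree, events, allowed_age_gap = c(2L, 6L)) {
  ev1 <- dplyr::slice_min(dplyr::group_by(events, .data$fish_id),
                          .data$spawn_date, n = 1, with_ties = FALSE)
  ev1 <- dplyr::ungroup(ev1)
  my <- mating_years(pedigree, events, allowed_age_gap)
  idx <- match(pedigree$offspring_fish, ev1$fish_id)
  rec <- tibble::tibble(
    offspring_fish = pedigree$offspring_fish,
    cohort_year = my,
    return_year = ev1$spawn_year[idx],
    age = ev1$spawn_year[idx] - my,
    program = ev1$program[idx],
    sex = ev1$resolved_sex[idx],
    length_mm = if ("length_mm" %in% names(ev1)) ev1$length_mm[idx] else NA_real_
  )
  rec <- rec[!is.na(rec$age), , drop = FALSE]
  pct_tab <- function(df, ...) {
    cnt <- dplyr::count(df, ..., .data$age, name = "n")
    g <- dplyr::group_by(cnt, ...)
    dplyr::ungroup(dplyr::mutate(g, pct = 100 * .data$n / sum(.data$n)))
  }
  size <- dplyr::summarise(
    dplyr::group_by(rec, .data$program, .data$age),
    n = dplyr::n(), mean_length_mm = mean(.data$length_mm, na.rm = TRUE),
    .groups = "drop")
  all_years <- sort(unique(events$spawn_year))
  censored <- all_years[all_years < min(all_years) + allowed_age_gap[1]]
  list(records = rec,
       by_program_age = pct_tab(rec, .data$program),
       by_program_sex_age = pct_tab(rec, .data$program, .data$sex),
       by_cohort = pct_tab(rec, .data$cohort_year),
       by_return = pct_tab(rec, .data$return_year),
       size_at_age = size,
       censored_return_years = censored)
}

#' Bin spawn dates within each season
#'
#' Half-open bins `[start, start + bin_days)` anchored at the earliest event
#' date of each program's season; the bin label is the bin start date.
#'
#' @param events fish-level spawn events.
#' @param bin_days bin width in days (5 or 10 in the published summaries).
#' @return events with `bin_start` plus a count table by program, season and
#'   bin.
#' @export
bin_spawn_dates <- function(events, bin_days = 5L) {
  stopifnot(bin_days >= 1)
  g <- dplyr::group_by(events, .data$program, .data$spawn_year)
  ev <- dplyr::mutate(g, bin_start = min(.data$spawn_date) +
    bin_days * ((as.numeric(.data$spawn_date - min(.data$spawn_date))) %/% bin_days))
  ev <- dplyr::ungroup(ev)
  counts <- dplyr::count(ev, .data$program, .data$spawn_year, .data$bin_start,
                         name = "n")
  list(events = ev, counts = counts)
}

#' Origin x return straying table
#'
#' Origin is the program where a fish's parents were sampled (the mating
#' program); return is the program where the fish itself first spawned.
#' Rates are column percentages: of all offspring originating from a
#' program, the share returning to each program.
#'
#' @param pedigree accepted trios.
#' @param events fish-level spawn events.
#' @param allowed_age_gap inclusive age range (for locating the mating).
#' @return list with `counts` (return x origin matrix), `rates` (column
#'   percentages), `records`.
#' @export
straying_matrix <- function(pedigree, events, allowed_age_gap = c(2L, 6L)) {
  my <- mating_years(pedigree, events, allowed_age_gap)
  prog_at <- function(fish, year) {
    i <- match(paste(fish, year), paste(events$fish_id, events$spawn_year))
    events$program[i]
  }
  origin <- prog_at(pedigree$mother_fish, my)
  ev1 <- dplyr::slice_min(dplyr::group_by(events, .data$fish_id),
                          .data$spawn_date, n = 1, with_ties = FALSE)
  ev1 <- dplyr::ungroup(ev1)
  ret <- ev1$program[match(pedigree$offspring_fish, ev1$fish_id)]
  ok <- !is.na(origin) & !is.na(ret)
  records <- tibble::tibble(offspring_fish = pedigree$offspring_fish[ok],
                            origin = origin[ok], return = ret[ok],
                            stray = origin[ok] != ret[ok])
  progs <- sort(unique(c(records$origin, records$return)))
  counts <- table(factor(records$return, progs), factor(records$origin, progs))
  list(counts = unclass(counts), rates = straying_rates(unclass(counts)),
       records = records)
}

#' Column percentages of an origin x return count matrix
#'
#' @param counts matrix with return programs as rows and origin programs as
#'   columns.
#' @return matrix of column percentages.
#' @export
straying_rates <- function(counts) {
  sweep(counts, 2, pmax(colSums(counts), 1), function(x, s) 100 * x / s)
}

#' Mean observed reproductive success by sex and spawning use
#'
#' Each accepted trio is credited to both parents at their mating season.
#' Per spawning event, the mean number of assigned offspring; per fish, the
#' mean total; both grouped by sex and spawning-use class. Fish without a
#' consistent resolved sex across events are excluded (and reported).
#'
#' @param pedigree accepted trios.
#' @param events fish-level spawn events.
#' @param use_records tibble from [classify_spawn_use()].
#' @param allowed_age_gap inclusive age range.
#' @return list with `by_sex_use` (per-event and total means), `per_fish`,
#'   `n_excluded_sex_discordant`.
#' @export
reproductive_success <- function(pedigree, events, use_records,
                                 allowed_age_gap = c(2L, 6L)) {
  my <- mating_years(pedigree, events, allowed_age_gap)
  credits <- dplyr::bind_rows(
    tibble::tibble(fish_id = pedigree$mother_fish, year = my),
    tibble::tibble(fish_id = pedigree$father_fish, year = my))
  credits <- credits[!is.na(credits$year), , drop = FALSE]
  ev_key <- dplyr::distinct(events[, c("fish_id", "spawn_year")])
  cr <- dplyr::count(credits, .data$fish_id, .data$year, name = "n_offspring")
  per_event <- dplyr::left_join(
    ev_key, cr, by = c("fish_id" = "fish_id", "spawn_year" = "year"))
  per_event$n_offspring[is.na(per_event$n_offspring)] <- 0L
  excluded <- use_records$fish_id[is.na(use_records$sex)]
  use_of <- use_records[!is.na(use_records$sex), c("fish_id", "sex", "use")]
  per_event <- dplyr::inner_join(per_event, use_of, by = "fish_id")
  per_fish <- dplyr::summarise(dplyr::group_by(per_event, .data$fish_id,
                                               .data$sex, .data$use),
                               total_offspring = sum(.data$n_offspring),
                               n_years = dplyr::n(), .groups = "drop")
  by_sex_use <- dplyr::full_join(
    dplyr::summarise(dplyr::group_by(per_event, .data$sex, .data$use),
                     mean_per_event = mean(.data$n_offspring),
                     n_events = dplyr::n(), .groups = "drop"),
    dplyr::summarise(dplyr::group_by(per_fish, .data$sex, .data$use),
                     mean_total = mean(.data$total_offspring),
                     n_fish = dplyr::n(), .groups = "drop"),
    by = c("sex", "use"))
  list(by_sex_use = by_sex_use, per_fish = per_fish,
       n_excluded_sex_discordant = length(excluded))
}

# exact multinomial goodness-of-fit by enumeration (small n)
exact_multinomial_test <- function(obs, probs) {
  n <- sum(obs)
  p_obs <- stats::dmultinom(obs, prob = probs)
  tot <- 0
  for (a in 0:n) for (b in 0:(n - a)) {
    pr <- stats::dmultinom(c(a, b, n - a - b), prob = probs)
    if (pr <= p_obs * (1 + 1e-12)) tot <- tot + pr
  }
  tot
}

#' Inversion-karyotype summaries
#'
#' Karyotypes (AA/AR/RR) are read from the inversion-indicator locus of each
#' fish's canonical genotype. Produces frequency tables by program and by
#' program and sex, an exact Hardy-Weinberg test per program, and the
#' segregation test among offspring of heterozygous (AR x AR) matings
#' against the Mendelian 1:2:1 expectation (chi-square, df 2; an exact
#' multinomial test is substituted and noted when any expected cell count is
#' below 5), overall and by sex.
#'
#' @param karyo integer vector of inversion-locus genotypes (0/1/2/NA) named
#'   by fish id.
#' @param events fish-level spawn events.
#' @param pedigree accepted trios.
#' @return list with `freq_table`, `hwe_by_program`, `segregation`.
#' @export
omy05_summary <- function(karyo, events, pedigree) {
  lab <- c("AA", "AR", "RR")
  ev1 <- dplyr::slice_min(dplyr::group_by(events, .data$fish_id),
                          .data$spawn_date, n = 1, with_ties = FALSE)
  ev1 <- dplyr::ungroup(ev1)
  ev1$karyotype <- lab[karyo[ev1$fish_id] + 1L]
  known <- ev1[!is.na(ev1$karyotype), , drop = FALSE]
  both <- dplyr::bind_rows(dplyr::mutate(known, sex_grp = "Total"),
                           dplyr::mutate(known, sex_grp = .data$resolved_sex))
  cnt <- dplyr::count(both, .data$program, .data$sex_grp, .data$karyotype,
                      name = "n")
  cnt <- dplyr::group_by(cnt, .data$program, .data$sex_grp)
  freq_table <- dplyr::ungroup(dplyr::mutate(cnt, pct = 100 * .data$n / sum(.data$n)))

  hwe_by_program <- dplyr::bind_rows(lapply(split(known, known$program), function(d) {
    h <- hwe_exact(sum(d$karyotype == "AA"), sum(d$karyotype == "AR"),
                   sum(d$karyotype == "RR"))
    tibble::tibble(program = d$program[1], n_AA = h$n_AA, n_AR = h$n_AB,
                   n_RR = h$n_BB, D = h$D, p_value = h$p_value)
  }))

  het <- !is.na(karyo[pedigree$mother_fish]) & karyo[pedigree$mother_fish] == 1L &
         !is.na(karyo[pedigree$father_fish]) & karyo[pedigree$father_fish] == 1L
  off <- pedigree$offspring_fish[het]
  seg_one <- function(ids, label) {
    g <- karyo[ids]
    g <- g[!is.na(g)]
    obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    if (sum(obs) == 0)
      return(tibble::tibble(group = label, n = 0L, n_AA = 0L, n_AR = 0L,
                            n_RR = 0L, statistic = NA_real_, df = NA_integer_,
                            p_value = NA_real_, method = "none"))
    expd <- sum(obs) * c(0.25, 0.5, 0.25)
    if (any(expd < 5)) {
      p <- exact_multinomial_test(obs, c(0.25, 0.5, 0.25))
      tibble::tibble(group = label, n = sum(obs), n_AA = obs[1], n_AR = obs[2],
                     n_RR = obs[3], statistic = NA_real_, df = NA_integer_,
                     p_value = p, method = "exact_multinomial")
    } else {
      ct <- stats::chisq.test(obs, p = c(0.25, 0.5, 0.25))
      tibble::tibble(group = label, n = sum(obs), n_AA = obs[1], n_AR = obs[2],
                     n_RR = obs[3], statistic = unname(ct$statistic),
                     df = unname(ct$parameter), p_value = ct$p.value,
                     method = "chi_square")
    }
  }
  sex_of <- stats::setNames(ev1$resolved_sex, ev1$fish_id)
  segregation <- dplyr::bind_rows(
    seg_one(off, "all"),
    seg_one(off[!is.na(sex_of[off]) & sex_of[off] == "F"], "F"),
    seg_one(off[!is.na(sex_of[off]) & sex_of[off] == "M"], "M"))
  list(freq_table = freq_table, hwe_by_program = hwe_by_program,
       segregation = segregation)
}

#' Kruskal-Wallis rank-sum test
#'
#' Thin wrapper around `stats::kruskal.test` returning the tie-corrected H
#' statistic, degrees of freedom and chi-square p-value. Degenerate input
#' (all values identical) returns `H = 0, p = 1`.
#'
#' @param values numeric (or ordinal-coded) observations.
#' @param groups grouping factor.
#' @return list with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2)
  if (length(unique(values)) == 1)
    return(list(H = 0, df = nlevels(groups) - 1L, p_value = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}
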