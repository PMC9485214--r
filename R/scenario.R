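#' Scenario configuration for the synthetic vital-registration generator
#'
#' Describes a synthetic study population: a base Siler mortality schedule,
#' proportional-hazards multipliers for each race/ethnicity, gender, and
#' urbanicity level, an annual secular improvement factor (applied as
#' `improvement^(year - min(years))`), and the county structure used to
#' distribute exposure. The defaults are calibrated to plausible late-20th
#' century US levels: infant mortality near 0.6%, baseline life expectancy in
#' the mid 70s, a 4-5 year gender gap, a Black disadvantage and an
#' Asian/Pacific Islander advantage in death rates, and a graded rural
#' mortality penalty.
#'
#' @param base_params Baseline [siler_params()] hazard.
#' @param race_multipliers Named positive multipliers for races
#'   `H, NHW, NHB, NHAPI`.
#' @param gender_multipliers Named positive multipliers for `man, woman`.
#' @param urbanicity_multipliers Named positive multipliers for the six
#'   urbanicity levels.
#' @param years Calendar years covered (subset of 1990-2019 by default).
#' @param improvement Annual hazard improvement factor (dimensionless, per
#'   year), in (0.9, 1.1]; values below 1 mean mortality falls over time.
#' @param counties_per_level Number of counties per urbanicity level (>= 1).
#' @param county_pop_scale Median county population (persons).
#' @param county_pop_sdlog Log-scale SD of county populations (log-normal).
#' @param race_shares,gender_shares Population composition (must each sum
#'   to 1).
#' @param state_weights Named vector of 2-character state FIPS prefixes and
#'   sampling weights used to place counties in states.
#' @param seed Root RNG seed for the generator.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(base_params = siler_params(),
                            race_multipliers = c(H = 0.9, NHW = 1, NHB = 1.3, NHAPI = 0.8),
                            gender_multipliers = c(man = 1.18, woman = 0.86),
                            urbanicity_multipliers = c(large_central = 0.98,
                                                       large_fringe = 0.94,
                                                       medium = 1.00, small = 1.04,
                                                       micropolitan = 1.10,
                                                       noncore = 1.16),
                            years = 1990:2019,
                            improvement = 0.995,
                            counties_per_level = 2,
                            county_pop_scale = 2e5,
                            county_pop_sdlog = 0.5,
                            race_shares = c(H = 0.18, NHW = 0.61, NHB = 0.13, NHAPI = 0.08),
                            gender_shares = c(man = 0.49, woman = 0.51),
                            state_weights = c("06" = 12, "48" = 9, "12" = 7, "36" = 6,
                                              "42" = 4, "17" = 4, "39" = 3.5, "26" = 3,
                                              "13" = 3, "37" = 3, "22" = 1.4, "40" = 1.2,
                                              "33" = 0.4),
                            seed = 20190101) {
  stopifnot(inherits(base_params, "siler_params"))
  check_named <- function(x, levels, what) {
    if (!setequal(names(x), levels)) {
      stop(what, " must be named with exactly: ", paste(levels, collapse = ", "))
    }
    if (any(!is.finite(x)) || any(x <= 0)) stop(what, " must all be positive")
    x[levels]
  }
  race_multipliers <- check_named(race_multipliers, race_levels(), "race_multipliers")
  gender_multipliers <- check_named(gender_multipliers, gender_levels(), "gender_multipliers")
  urbanicity_multipliers <- check_named(urbanicity_multipliers, urbanicity6_levels(),
                                        "urbanicity_multipliers")
  race_shares <- check_named(race_shares, race_levels(), "race_shares")
  gender_shares <- check_named(gender_shares, gender_levels(), "gender_shares")
  if (abs(sum(race_shares) - 1) > 1e-8 || abs(sum(gender_shares) - 1) > 1e-8) {
    stop("race_shares and gender_shares must each sum to 1")
  }
  if (length(improvement) != 1L || improvement <= 0.9 || improvement > 1.1) {
    stop("improvement factor must lie in (0.9, 1.1]")
  }
  if (counties_per_level < 1) stop("counties_per_level must be >= 1")
  if (county_pop_scale <= 0) stop("county_pop_scale must be positive")
  if (any(nchar(names(state_weights)) != 2L)) stop("state_weights names must be 2-character state prefixes")
  structure(list(base_params = base_params,
                 race_multipliers = race_multipliers,
                 gender_multipliers = gender_multipliers,
                 urbanicity_multipliers = urbanicity_multipliers,
                 years = sort(unique(as.integer(years))),
                 improvement = improvement,
                 counties_per_level = as.integer(counties_per_level),
                 county_pop_scale = county_pop_scale,
                 county_pop_sdlog = county_pop_sdlog,
                 race_shares = race_shares,
                 gender_shares = gender_shares,
                 state_weights = state_weights,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# Combined proportional-hazards multiplier for one group in one year.
group_multiplier <- function(config, race, gender, urbanicity, year = NULL) {
  k <- config$race_multipliers[[race]] *
    config$gender_multipliers[[gender]] *
    config$urbanicity_multipliers[[urbanicity]]
  if (!is.null(year)) k <- k * config$improvement^(year - min(config$years))
  k
}

# Stationary-population age weights (normalised person-years per interval)
# of the schedule implied by hazard multiplier k.
stationary_weights <- function(config, k) {
  params <- scale_hazard(config$base_params, k)
  cutoff <- lifespan_cutoff(params)
  grid <- age_grid()
  w <- vapply(seq_len(nrow(grid)), function(i) {
    lo <- grid$age_start[i]
    hi <- if (is.finite(grid$width[i])) lo + grid$width[i] else max(cutoff, lo + 1)
    t <- fine_grid(lo, hi, 0.01)
    sum(siler_survival(params, t) * trapezoid_weights(t))
  }, numeric(1))
  w / sum(w)
}

#' Generate a complete synthetic study dataset with ground truth
#'
#' Emits (i) a stratified counts table in the ingest schema covering every
#' year x county x age x gender x race/ethnicity cell, (ii) a county-to-
#' urbanicity crosswalk, and (iii) a ground-truth table with the exact
#' `e0`, `sd0`, and `cv0` of every race x gender x urbanicity x period group,
#' computed from the generating hazards by numerical integration (no age
#' grouping, no sampling noise). Death counts are Poisson draws around the
#' exact interval rates; county exposures are log-normal around the
#' configured scale with a fixed stationary age structure.
#'
#' @param config A [scenario_config()].
#' @param dir Optional directory; when given, `counts.csv`, `crosswalk.csv`,
#'   and `truth.csv` are written there.
#' @return (Invisibly when `dir` is given.) List with data frames `counts`,
#'   `crosswalk`, `truth`, and `paths` (NULL unless written).
#' @export
make_study_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  grid <- age_grid()
  nage <- nrow(grid)
  races <- race_levels()
  genders <- gender_levels()
  urbs <- urbanicity6_levels()

  # County frame: identifiers, urbanicity, state, population.
  counties <- with_seed(config$seed, {
    n <- config$counties_per_level * length(urbs)
    states <- sample(names(config$state_weights), n, replace = TRUE,
                     prob = config$state_weights)
    pop <- stats::rlnorm(n, meanlog = log(config$county_pop_scale),
                         sdlog = config$county_pop_sdlog)
    data.frame(county_fips = paste0(states, sprintf("%03d", seq_len(n))),
               urbanicity6 = rep(urbs, each = config$counties_per_level),
               population = pop, stringsAsFactors = FALSE)
  })
  if (anyDuplicated(counties$county_fips)) {
    stop("generation error: overlapping county identifiers across urbanicity levels")
  }

  # Fixed age structure of exposure per group (stationary weights of the
  # group's period-start schedule; constant across years).
  weight_tab <- list()
  for (u in urbs) for (r in races) for (g in genders) {
    key <- paste(u, r, g, sep = "|")
    weight_tab[[key]] <- stationary_weights(config, group_multiplier(config, r, g, u))
  }

  # Exact interval rates per group-year (cached by multiplier value).
  sched_cache <- new.env(parent = emptyenv())
  mx_for <- function(k) {
    key <- sprintf("%.12g", k)
    if (is.null(sched_cache[[key]])) {
      sched_cache[[key]] <- schedule_from_siler(scale_hazard(config$base_params, k), grid)$mx
    }
    sched_cache[[key]]
  }

  cols <- list(year = list(), fips = list(), age = list(), gender = list(),
               race = list(), deaths = list(), pop = list())
  bi <- 0L
  with_seed(config$seed + 1L, {
    for (u in urbs) {
      cty <- counties[counties$urbanicity6 == u, ]
      for (r in races) for (g in genders) {
        wts <- weight_tab[[paste(u, r, g, sep = "|")]]
        share <- config$race_shares[[r]] * config$gender_shares[[g]]
        # person-years per age x county cell, constant over years
        nmat <- round(outer(wts, cty$population * share))
        for (y in config$years) {
          mx <- mx_for(group_multiplier(config, r, g, u, y))
          d <- stats::rpois(length(nmat), as.vector(mx * nmat))
          bi <- bi + 1L
          nc <- nrow(cty)
          cols$year[[bi]] <- rep.int(y, nage * nc)
          cols$fips[[bi]] <- rep(cty$county_fips, each = nage)
          cols$age[[bi]] <- rep.int(grid$age_group, nc)
          cols$gender[[bi]] <- rep.int(g, nage * nc)
          cols$race[[bi]] <- rep.int(r, nage * nc)
          cols$deaths[[bi]] <- d
          cols$pop[[bi]] <- as.vector(nmat)
        }
      }
    }
  })
  counts <- data.frame(year = unlist(cols$year),
                       county_fips = unlist(cols$fips),
                       age_group = unlist(cols$age),
                       gender = unlist(cols$gender),
                       race_ethnicity = unlist(cols$race),
                       deaths = unlist(cols$deaths),
                       population = unlist(cols$pop),
                       stringsAsFactors = FALSE)

  crosswalk <- counties[, c("county_fips", "urbanicity6")]

  # Ground truth per group x period: the pooled-period hazard multiplier is
  # the mean of the yearly multipliers (exposures are constant within group
  # across years, so pooled rates equal the mean of yearly rates).
  periods <- default_periods()
  truth_rows <- list()
  ti <- 0L
  for (p in seq_len(nrow(periods))) {
    yrs <- intersect(config$years, periods$start[p]:periods$end[p])
    if (length(yrs) == 0) next
    for (u in urbs) for (r in races) for (g in genders) {
      k0 <- group_multiplier(config, r, g, u)
      k_eff <- k0 * mean(config$improvement^(yrs - min(config$years)))
      tr <- siler_truth(scale_hazard(config$base_params, k_eff), ages = 0)
      ti <- ti + 1L
      truth_rows[[ti]] <- data.frame(race_ethnicity = r, gender = g,
                                     urbanicity6 = u, period = periods$label[p],
                                     e0 = tr$ex, sd0 = tr$sdx, cv0 = tr$cvx,
                                     stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth_rows)

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(counts = file.path(dir, "counts.csv"),
                  crosswalk = file.path(dir, "crosswalk.csv"),
                  truth = file.path(dir, "truth.csv"))
    utils::write.csv(counts, paths$counts, row.names = FALSE)
    utils::write.csv(crosswalk, paths$crosswalk, row.names = FALSE)
    utils::write.csv(truth, paths$truth, row.names = FALSE)
  }
  out <- list(counts = counts, crosswalk = crosswalk, truth = truth, paths = paths)
  if (is.null(dir)) out else invisible(out)
}
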