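#' The six 5-year pooling periods
#'
#' @return Data frame with columns `label`, `start`, `end` covering
#'   1990-1994 through 2015-2019.
#' @export
default_periods <- function() {
  start <- seq(1990, 2015, by = 5)
  data.frame(label = paste(start, start + 4, sep = "-"),
             start = start, end = start + 4, stringsAsFactors = FALSE)
}

counts_columns <- c("year", "county_fips", "age_group", "gender",
                    "race_ethnicity", "deaths", "population")

#' Read and validate a stratified counts file
#'
#' Reads a CSV of death and midyear-population counts stratified by
#' year x county x age group x gender x race/ethnicity, enforcing the fixed
#' label vocabularies, nonnegative integer counts, and cell uniqueness.
#'
#' @param path Path to a counts CSV with columns `year, county_fips,
#'   age_group, gender, race_ethnicity, deaths, population`.
#' @return A validated data frame.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  x <- utils::read.csv(path, colClasses = c(county_fips = "character"),
                       stringsAsFactors = FALSE)
  validate_counts(x)
}

#' @rdname read_counts
#' @param counts A counts data frame to validate in place.
#' @export
validate_counts <- function(counts) {
  missing_cols <- setdiff(counts_columns, names(counts))
  if (length(missing_cols) > 0) {
    stop("counts table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  counts <- counts[counts_columns]
  check_vocab <- function(col, levels, what) {
    bad <- !(counts[[col]] %in% levels)
    if (any(bad)) {
      stop("parse error: unknown ", what, " label(s) ",
           paste(unique(counts[[col]][bad]), collapse = ", "),
           " at row(s) ", paste(utils::head(which(bad), 5), collapse = ", "))
    }
  }
  check_vocab("age_group", age_labels(), "age group")
  check_vocab("gender", gender_levels(), "gender")
  check_vocab("race_ethnicity", race_levels(), "race/ethnicity")
  for (col in c("year", "deaths", "population")) {
    v <- counts[[col]]
    bad <- !is.finite(v) | v < 0 | v != round(v)
    if (any(bad)) {
      stop("parse error: column '", col, "' must hold nonnegative integers; bad row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    }
  }
  if (any(nchar(counts$county_fips) != 5L)) {
    stop("parse error: county_fips must be 5-character strings; bad row(s) ",
         paste(utils::head(which(nchar(counts$county_fips) != 5L), 5), collapse = ", "))
  }
  key <- do.call(paste, c(counts[c("year", "county_fips", "age_group", "gender",
                                   "race_ethnicity")], sep = "|"))
  if (anyDuplicated(key)) {
    stop("integrity error: duplicated cell(s), e.g. ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  }
  if (any(counts$deaths > 0 & counts$population == 0)) {
    stop("integrity error: deaths recorded in cells with zero population")
  }
  counts
}

#' Read auxiliary input tables
#'
#' `read_crosswalk()` reads the county-to-urbanicity crosswalk
#' (`county_fips, urbanicity6`); `read_merges()` reads a county merge map
#' (`old_fips, new_fips`); `read_exclusions()` reads a state x year-range x
#' race exclusion list (`state_prefix, year_start, year_end, race_ethnicity`).
#' `default_exclusions()` returns the NCHS-recommended Hispanic exclusions
#' (Louisiana 1990, New Hampshire 1990-1992, Oklahoma 1990-1996) shipped with
#' the package.
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_crosswalk <- function(path) {
  x <- utils::read.csv(path, colClasses = c(county_fips = "character"),
                       stringsAsFactors = FALSE)
  stopifnot(all(c("county_fips", "urbanicity6") %in% names(x)))
  bad <- setdiff(unique(x$urbanicity6), urbanicity6_levels())
  if (length(bad) > 0) stop("unknown urbanicity code(s) in crosswalk: ", paste(bad, collapse = ", "))
  x
}

#' @rdname read_crosswalk
#' @export
read_merges <- function(path) {
  x <- utils::read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  stopifnot(all(c("old_fips", "new_fips") %in% names(x)))
  x
}

#' @rdname read_crosswalk
#' @export
read_exclusions <- function(path) {
  x <- utils::read.csv(path, colClasses = c(state_prefix = "character"),
                       stringsAsFactors = FALSE)
  stopifnot(all(c("state_prefix", "year_start", "year_end", "race_ethnicity") %in% names(x)))
  x
}

#' @rdname read_crosswalk
#' @export
default_exclusions <- function() {
  read_exclusions(system.file("extdata", "hispanic_exclusions.csv",
                              package = "lifevar", mustWork = TRUE))
}

#' Apply county boundary merges
#'
#' Re-labels counts from old county identifiers to their merge targets and
#' sums the affected cells, conserving total deaths and population.
#'
#' @param counts A validated counts table.
#' @param merges Data frame with columns `old_fips`, `new_fips` (may be
#'   empty, in which case the table is returned unchanged).
#' @return Counts table with merged counties.
#' @export
apply_county_merges <- function(counts, merges) {
  if (is.null(merges) || nrow(merges) == 0) return(counts)
  idx <- match(counts$county_fips, merges$old_fips)
  hit <- !is.na(idx)
  if (!any(hit)) return(counts)
  counts$county_fips[hit] <- merges$new_fips[idx[hit]]
  agg <- stats::aggregate(counts[c("deaths", "population")],
                          counts[c("year", "county_fips", "age_group", "gender",
                                   "race_ethnicity")],
                          FUN = sum)
  agg[counts_columns]
}

#' Apply state-year-race exclusions
#'
#' Removes matching rows (both deaths and population) from the counts table,
#' following the NCHS guidance for Hispanic rate calculations. The state is
#' identified by the first two characters of `county_fips`. The removed share
#' of the matching race's person-years is reported via `message()` and
#' attached as attribute `"excluded"`.
#'
#' @param counts A validated counts table.
#' @param exclusions Data frame with columns `state_prefix, year_start,
#'   year_end, race_ethnicity`; see [default_exclusions()].
#' @return Counts table with matching rows removed.
#' @export
apply_exclusions <- function(counts, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0) return(counts)
  state <- substr(counts$county_fips, 1, 2)
  drop <- rep(FALSE, nrow(counts))
  for (i in seq_len(nrow(exclusions))) {
    drop <- drop | (state == exclusions$state_prefix[i] &
                      counts$year >= exclusions$year_start[i] &
                      counts$year <= exclusions$year_end[i] &
                      counts$race_ethnicity == exclusions$race_ethnicity[i])
  }
  races <- unique(exclusions$race_ethnicity)
  race_py <- sum(counts$population[counts$race_ethnicity %in% races])
  removed <- data.frame(rows = sum(drop),
                        deaths = sum(counts$deaths[drop]),
                        person_years = sum(counts$population[drop]),
                        fraction_of_race_py = if (race_py > 0) sum(counts$population[drop]) / race_py else 0)
  message(sprintf("exclusions removed %d rows (%.0f person-years, %.3f%% of %s person-years)",
                  removed$rows, removed$person_years,
                  100 * removed$fraction_of_race_py, paste(races, collapse = "/")))
  out <- counts[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- removed
  out
}

#' Attach urbanicity codes to a counts table
#'
#' Joins the county-to-urbanicity crosswalk and either keeps the detailed
#' 6-level codes or collapses them to the metropolitan/nonmetropolitan
#' dichotomy (`large_central`, `large_fringe`, `medium`, `small` are
#' metropolitan; `micropolitan`, `noncore` are nonmetropolitan).
#'
#' @param counts A validated counts table.
#' @param crosswalk Data frame with columns `county_fips`, `urbanicity6`.
#' @param levels 2 or 6.
#' @return Counts table with an added `urbanicity` column.
#' @export
map_urbanicity <- function(counts, crosswalk, levels = 2) {
  if (!levels %in% c(2, 6)) stop("levels must be 2 or 6")
  idx <- match(counts$county_fips, crosswalk$county_fips)
  if (anyNA(idx)) {
    stop("mapping error: counties missing from crosswalk: ",
         paste(utils::head(unique(counts$county_fips[is.na(idx)]), 10), collapse = ", "))
  }
  code6 <- crosswalk$urbanicity6[idx]
  counts$urbanicity <- if (levels == 6) code6 else urbanicity6_to_2(code6)
  counts
}

#' Pool counts over 5-year periods and aggregate strata
#'
#' Sums deaths and person-years (midyear populations summed across the pooled
#' years) over counties within each urbanicity level and years within each
#' period, yielding one row per race x gender x urbanicity x period x age
#' interval.
#'
#' @param counts Counts table with an `urbanicity` column (see
#'   [map_urbanicity()]).
#' @param periods Period definition as from [default_periods()].
#' @return Aggregated vital counts with columns `race_ethnicity, gender,
#'   urbanicity, period, age_group, age_start, width, deaths, person_years`.
#' @export
pool_and_aggregate <- function(counts, periods = default_periods()) {
  if (!"urbanicity" %in% names(counts)) stop("counts must carry an urbanicity column; run map_urbanicity() first")
  pidx <- rep(NA_integer_, nrow(counts))
  for (i in seq_len(nrow(periods))) {
    inp <- counts$year >= periods$start[i] & counts$year <= periods$end[i]
    if (any(inp & !is.na(pidx))) stop("config error: periods overlap")
    pidx[inp] <- i
  }
  if (anyNA(pidx)) {
    stop("config error: year(s) outside all periods: ",
         paste(sort(unique(counts$year[is.na(pidx)])), collapse = ", "))
  }
  counts$period <- periods$label[pidx]
  agg <- stats::aggregate(counts[c("deaths", "population")],
                          counts[c("race_ethnicity", "gender", "urbanicity",
                                   "period", "age_group")],
                          FUN = sum)
  names(agg)[names(agg) == "population"] <- "person_years"
  grid <- age_grid()
  gi <- match(agg$age_group, grid$age_group)
  agg$age_start <- grid$age_start[gi]
  agg$width <- grid$width[gi]
  agg <- agg[order(agg$race_ethnicity, agg$gender, agg$urbanicity, agg$period,
                   agg$age_start), ]
  rownames(agg) <- NULL
  agg[c("race_ethnicity", "gender", "urbanicity", "period", "age_group",
        "age_start", "width", "deaths", "person_years")]
}

# Single-stratum key string, used for messages and seed derivation.
stratum_key <- function(df) {
  paste(df$race_ethnicity[1], df$gender[1], df$urbanicity[1], df$period[1], sep = "|")
}

#' Central death rates per stratum
#'
#' Computes `m_x = D_x / N_x` for every stratum in an aggregated vital-counts
#' table. Strata that cannot support a life table are excluded with a
#' warning: any interval with zero exposure (and zero deaths), or an open
#' interval with zero deaths (the table cannot be closed). Zero exposure with
#' positive deaths is a data error.
#'
#' @param vital Aggregated counts from [pool_and_aggregate()].
#' @return The input table with an added `mx` column, unusable strata
#'   removed; dropped stratum keys are attached as attribute `"dropped"`.
#' @export
compute_rates <- function(vital) {
  if (any(vital$person_years == 0 & vital$deaths > 0)) {
    stop("data error: zero exposure with positive deaths")
  }
  key <- do.call(paste, c(vital[c("race_ethnicity", "gender", "urbanicity", "period")],
                          sep = "|"))
  open <- !is.finite(vital$width)
  bad_keys <- unique(key[vital$person_years == 0 | (open & vital$deaths == 0)])
  if (length(bad_keys) > 0) {
    warning("excluding ", length(bad_keys),
            " stratum/strata unusable for life tables (zero exposure or empty open interval): ",
            paste(utils::head(bad_keys, 5), collapse = "; "))
    keep <- !(key %in% bad_keys)
    vital <- vital[keep, , drop = FALSE]
    rownames(vital) <- NULL
  }
  vital$mx <- vital$deaths / vital$person_years
  attr(vital, "dropped") <- bad_keys
  vital
}
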