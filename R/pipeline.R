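#' Configuration for an end-to-end pipeline run
#'
#' Collects every knob of the simulate/ingest/life-table/variation/
#' uncertainty/inequality pipeline in one list. Input is either a synthetic
#' scenario (`scenario`) or paths to a counts CSV and crosswalk CSV; county
#' merges and exclusions are data inputs, so sensitivity analyses (e.g. an
#' alternative urbanicity scheme year) are a config swap, not a code change.
#'
#' @param scenario A [scenario_config()], used when `counts_path` is NULL.
#' @param counts_path,crosswalk_path Paths to input CSVs (real-data mode).
#' @param merges_path Optional county merge map CSV.
#' @param exclusions `"default"` for the packaged NCHS Hispanic exclusions, a
#'   path to an exclusions CSV, or `NULL` for none.
#' @param urbanicity_levels 2 (metropolitan/nonmetropolitan) or 6.
#' @param ages Grid start ages at which life expectancy and lifespan
#'   variation are reported (subset of 0, 10, 35, 65 by convention).
#' @param periods Period table as from [default_periods()].
#' @param bootstrap_reps Bootstrap replicates per stratum (>= 100), or 0 to
#'   skip the uncertainty stage.
#' @param include_overall Also compute all-race ("ALL") pooled strata.
#' @param normalize CV normalisation, see [cv_at_age()].
#' @param a0,infant_rule Infant separation-factor rule, see [default_ax()].
#' @param rounding Decimal places used only when writing `results_rounded`;
#'   internal values are never rounded.
#' @param seed Root seed; per-stratum bootstrap seeds are derived from it by
#'   hashing the stratum key, so adding strata never reshuffles the draws of
#'   existing ones.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(scenario = scenario_config(),
                            counts_path = NULL, crosswalk_path = NULL,
                            merges_path = NULL, exclusions = "default",
                            urbanicity_levels = 2,
                            ages = c(0, 10, 35, 65),
                            periods = default_periods(),
                            bootstrap_reps = 0,
                            include_overall = TRUE,
                            normalize = "remaining",
                            a0 = 0.1, infant_rule = "fixed",
                            rounding = c(years = 1, ratio = 2),
                            seed = 20190101) {
  if (!urbanicity_levels %in% c(2, 6)) stop("urbanicity_levels must be 2 or 6")
  grid_ages <- age_grid()$age_start
  if (!all(ages %in% grid_ages)) stop("ages must be grid start ages")
  if (bootstrap_reps != 0 && bootstrap_reps < 100) {
    stop("bootstrap_reps must be 0 (disabled) or >= 100")
  }
  structure(list(scenario = scenario, counts_path = counts_path,
                 crosswalk_path = crosswalk_path, merges_path = merges_path,
                 exclusions = exclusions,
                 urbanicity_levels = urbanicity_levels, ages = ages,
                 periods = periods, bootstrap_reps = bootstrap_reps,
                 include_overall = include_overall, normalize = normalize,
                 a0 = a0, infant_rule = infant_rule, rounding = rounding,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments;
#' `scenario:` may override any [scenario_config()] argument (multiplier
#' blocks are taken as named mappings).
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  scen_args <- y$scenario
  if (!is.null(scen_args)) {
    for (nm in c("race_multipliers", "gender_multipliers",
                 "urbanicity_multipliers", "race_shares", "gender_shares",
                 "state_weights")) {
      if (!is.null(scen_args[[nm]])) scen_args[[nm]] <- unlist(scen_args[[nm]])
    }
    if (!is.null(scen_args$base_params)) {
      scen_args$base_params <- do.call(siler_params, scen_args$base_params)
    }
    if (!is.null(scen_args$years) && length(scen_args$years) == 2) {
      scen_args$years <- scen_args$years[1]:scen_args$years[2]
    }
    # YAML 1.1 reads "1.0e4"-style scalars as strings; coerce numerics
    for (nm in c("county_pop_scale", "county_pop_sdlog", "improvement",
                 "counties_per_level", "seed")) {
      if (!is.null(scen_args[[nm]])) scen_args[[nm]] <- as.numeric(scen_args[[nm]])
    }
  }
  args <- y[setdiff(names(y), "scenario")]
  args$scenario <- do.call(scenario_config, if (is.null(scen_args)) list() else scen_args)
  if (!is.null(args$rounding)) args$rounding <- unlist(args$rounding)
  do.call(pipeline_config, args)
}

# Wide measure/CI column block for one stratum.
stratum_measures <- function(stratum, config) {
  lt <- build_life_table(stratum, a0 = config$a0, infant_rule = config$infant_rule)
  out <- list()
  for (y in config$ages) {
    vr <- cv_at_age(lt, y, normalize = config$normalize)
    out[[paste0("e", y)]] <- vr$ex
    out[[paste0("sd", y)]] <- vr$sdx
    out[[paste0("cv", y)]] <- vr$cvx
  }
  if (config$bootstrap_reps > 0) {
    bseed <- derive_seed(config$seed, stratum_key(stratum))
    for (y in config$ages) {
      for (st in c("ex", "cv")) {
        b <- poisson_bootstrap(stratum, statistic = st, age = y,
                               reps = config$bootstrap_reps, seed = bseed,
                               a0 = config$a0, infant_rule = config$infant_rule,
                               normalize = config$normalize)
        pre <- paste0(if (st == "ex") "e" else "cv", y)
        out[[paste0(pre, "_lo")]] <- b$lower
        out[[paste0(pre, "_hi")]] <- b$upper
        out[[paste0("se_", pre)]] <- b$se
      }
    }
    out$reps <- config$bootstrap_reps
    out$seed <- bseed
  }
  as.data.frame(out)
}

#' Run the full mortality-inequality pipeline
#'
#' Simulates (or reads) stratified vital-registration counts, applies county
#' merges, race-state-year exclusions, and the urbanicity crosswalk, pools
#' counts into 5-year periods, builds an abridged life table per stratum,
#' computes life expectancy and lifespan variation at the configured ages
#' (with parametric-bootstrap intervals when enabled), and summarises
#' absolute and relative inequalities.
#'
#' @param config A `run_config` from [pipeline_config()] or
#'   [load_run_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `life_tables.csv`, `results.csv`, `inequality.csv`, and `manifest.json`.
#' @return List with elements `vital` (pooled counts + rates), `life_tables`
#'   (stacked per-stratum tables), `results` (wide per-stratum measures),
#'   `inequality` (report from [inequality_report()]), `truth` (generator
#'   ground truth, simulate mode only), `dropped` (unusable stratum keys),
#'   and `excluded` (exclusion bookkeeping).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))

  truth <- NULL
  if (is.null(config$counts_path)) {
    bundle <- make_study_dataset(config$scenario)
    counts <- validate_counts(bundle$counts)
    crosswalk <- bundle$crosswalk
    truth <- bundle$truth
  } else {
    counts <- read_counts(config$counts_path)
    if (is.null(config$crosswalk_path)) stop("crosswalk_path is required with counts_path")
    crosswalk <- read_crosswalk(config$crosswalk_path)
  }

  if (!is.null(config$merges_path)) {
    counts <- apply_county_merges(counts, read_merges(config$merges_path))
  }
  excluded <- NULL
  if (!is.null(config$exclusions)) {
    excl <- if (identical(config$exclusions, "default")) {
      default_exclusions()
    } else {
      read_exclusions(config$exclusions)
    }
    counts <- apply_exclusions(counts, excl)
    excluded <- attr(counts, "excluded")
    if (!is.null(excluded) && excluded$fraction_of_race_py > 0.01) {
      warning(sprintf("exclusions removed %.2f%% of the matching race's person-years (expected under 1%%)",
                      100 * excluded$fraction_of_race_py))
    }
  }

  counts <- map_urbanicity(counts, crosswalk, levels = config$urbanicity_levels)
  vital <- pool_and_aggregate(counts, config$periods)
  if (config$include_overall) {
    overall <- vital
    overall$race_ethnicity <- "ALL"
    overall <- stats::aggregate(overall[c("deaths", "person_years")],
                                overall[c("race_ethnicity", "gender", "urbanicity",
                                          "period", "age_group", "age_start", "width")],
                                FUN = sum)
    vital <- rbind(vital[names(overall)], overall)
  }
  vital <- vital[order(vital$race_ethnicity, vital$gender, vital$urbanicity,
                       vital$period, vital$age_start), ]
  rownames(vital) <- NULL
  vital <- compute_rates(vital)

  keys <- unique(vital[c("race_ethnicity", "gender", "urbanicity", "period")])
  res_rows <- list()
  lt_rows <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- vital$race_ethnicity == keys$race_ethnicity[i] &
      vital$gender == keys$gender[i] &
      vital$urbanicity == keys$urbanicity[i] &
      vital$period == keys$period[i]
    stratum <- vital[sel, , drop = FALSE]
    stratum <- stratum[order(stratum$age_start), , drop = FALSE]
    meas <- tryCatch(
      stratum_measures(stratum, config),
      error = function(e) stop("pipeline stage 'measures' failed for stratum ",
                               stratum_key(stratum), ": ", conditionMessage(e)))
    res_rows[[i]] <- cbind(keys[i, , drop = FALSE], meas)
    lt <- build_life_table(stratum, a0 = config$a0, infant_rule = config$infant_rule)
    lt_rows[[i]] <- cbind(keys[i, , drop = FALSE], as.data.frame(lt), row.names = NULL)
  }
  results <- do.call(rbind, res_rows)
  rownames(results) <- NULL
  life_tables <- do.call(rbind, lt_rows)
  rownames(life_tables) <- NULL

  ineq <- if (config$urbanicity_levels == 2) {
    inequality_report(results)
  } else {
    inequality_report(results, urbanicity_a = "large_central", urbanicity_b = "noncore")
  }

  out <- list(vital = vital, life_tables = life_tables, results = results,
              inequality = ineq, truth = truth,
              dropped = attr(vital, "dropped"), excluded = excluded)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(life_tables, file.path(out_dir, "life_tables.csv"), row.names = FALSE)
    utils::write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
    utils::write.csv(ineq, file.path(out_dir, "inequality.csv"), row.names = FALSE)
    manifest <- list(package = "lifevar",
                     version = as.character(utils::packageVersion("lifevar")),
                     seed = config$seed,
                     config_hash = string_hash(paste(deparse(config), collapse = "")),
                     urbanicity_levels = config$urbanicity_levels,
                     ages = config$ages,
                     bootstrap_reps = config$bootstrap_reps,
                     n_strata = nrow(results),
                     dropped_strata = length(out$dropped))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out)
}
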