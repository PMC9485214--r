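#' Parametric Poisson bootstrap for life-table statistics
#'
#' Attaches a Monte-Carlo standard error and a 95% percentile interval to a
#' life-table statistic (life expectancy or coefficient of variation at a
#' grid age) for one stratum. Each replicate redraws the death counts
#' `D*_x ~ Poisson(D_x)` with exposures held fixed, recomputes the rates,
#' rebuilds the life table, and re-evaluates the statistic. Percentile bounds
#' are used rather than a normal approximation because CV replicates can be
#' skewed in small strata.
#'
#' Replicates whose open-interval count comes back zero cannot close a life
#' table; they are redrawn (and counted), up to `max_redraws` rounds, after
#' which the bootstrap fails.
#'
#' @param counts Vital counts for one stratum: a data frame with columns
#'   `age_start`, `deaths`, `person_years` aligned to the abridged grid (a
#'   `width` column is optional and recomputed from the grid).
#' @param statistic `"ex"` (life expectancy) or `"cv"` (coefficient of
#'   variation).
#' @param age Grid start age at which the statistic is evaluated.
#' @param reps Number of bootstrap replicates (>= 100).
#' @param seed RNG seed; fixed seed gives bit-identical intervals.
#' @param resample Set to `FALSE` to force `D* = D` in every replicate (a
#'   degenerate bootstrap with zero spread, useful for checking the
#'   machinery).
#' @param max_redraws Cap on redraw rounds for replicates with an empty open
#'   interval.
#' @param a0,infant_rule,normalize Passed through to [build_life_table()] and
#'   [cv_at_age()].
#' @return An `uncertainty_result` list: `statistic`, `age`, `estimate`,
#'   `se`, `lower`, `upper`, `reps`, `seed`, `redraws`.
#' @export
poisson_bootstrap <- function(counts, statistic = c("ex", "cv"), age = 0,
                              reps = 1000, seed = 1, resample = TRUE,
                              max_redraws = 100, a0 = 0.1,
                              infant_rule = "fixed",
                              normalize = "remaining") {
  statistic <- match.arg(statistic)
  stopifnot(is.data.frame(counts),
            all(c("age_start", "deaths", "person_years") %in% names(counts)))
  if (reps < 100) stop("reps must be >= 100")
  grid <- age_grid()
  counts <- counts[order(counts$age_start), , drop = FALSE]
  if (!identical(as.numeric(counts$age_start), as.numeric(grid$age_start))) {
    stop("counts must cover exactly the abridged grid intervals")
  }
  if (any(counts$person_years <= 0)) stop("all intervals need positive exposure")
  if (counts$deaths[nrow(counts)] == 0) {
    stop("open-interval deaths are zero; the observed life table cannot be closed")
  }

  eval_stat <- function(mx) {
    lt <- build_life_table(mx, grid, a0 = a0, infant_rule = infant_rule)
    if (statistic == "ex") life_expectancy_at(lt, age) else cv_at_age(lt, age, normalize)$cvx
  }
  point <- eval_stat(counts$deaths / counts$person_years)

  k <- nrow(counts)
  open_row <- k
  redraws <- 0L
  stats_rep <- with_seed(seed, {
    dstar <- if (resample) {
      matrix(stats::rpois(k * reps, rep(counts$deaths, reps)), nrow = k)
    } else {
      matrix(rep(counts$deaths, reps), nrow = k)
    }
    if (resample) {
      rounds <- 0L
      repeat {
        empty <- which(dstar[open_row, ] == 0)
        if (length(empty) == 0) break
        rounds <- rounds + 1L
        if (rounds > max_redraws) {
          stop("bootstrap failure: open-interval count still zero after ",
               max_redraws, " redraw rounds")
        }
        redraws <- redraws + length(empty)
        dstar[, empty] <- stats::rpois(k * length(empty),
                                       rep(counts$deaths, length(empty)))
      }
    }
    apply(dstar, 2, function(d) eval_stat(d / counts$person_years))
  })
  if (redraws > 0) {
    message("poisson_bootstrap: redrew ", redraws,
            " replicate(s) with an empty open interval")
  }
  qs <- unname(stats::quantile(stats_rep, c(0.025, 0.975)))
  structure(list(statistic = statistic, age = age, estimate = point,
                 se = stats::sd(stats_rep), lower = qs[1], upper = qs[2],
                 reps = as.integer(reps), seed = as.integer(seed),
                 redraws = redraws),
            class = "uncertainty_result")
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat(sprintf("%s at age %g: %.4f (SE %.4f, 95%% CI %.4f-%.4f; %d reps, seed %d)\n",
              x$statistic, x$age, x$estimate, x$se, x$lower, x$upper,
              x$reps, x$seed))
  invisible(x)
}
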