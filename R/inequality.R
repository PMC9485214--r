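#' Absolute and relative inequality between two strata
#'
#' `absolute_gap(a, b)` returns `a - b` (units of the measure);
#' `relative_ratio(a, b)` returns `a / b` (dimensionless). By the package's
#' convention `a` is the metropolitan (or higher-ranked) member, so positive
#' gaps and ratios above 1 both indicate an advantage for `a`.
#'
#' @param a,b Values of one measure (e.g. life expectancy in years) for the
#'   two strata.
#' @return A numeric scalar (vectorised over `a`, `b`).
#' @examples
#' absolute_gap(89.8, 72.1)   # 17.7
#' relative_ratio(77.0, 74.5) # about 1.03
#' @export
absolute_gap <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("both values must be finite")
  a - b
}

#' @rdname absolute_gap
#' @export
relative_ratio <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("both values must be finite")
  if (any(b <= 0)) stop("denominator value(s) must be positive")
  a / b
}

#' Range gap across groups within a cell
#'
#' Identifies the highest- and lowest-valued groups (e.g. races within one
#' gender x urbanicity x period cell) and their difference. Ties are broken
#' by a fixed group order and flagged.
#'
#' @param values Named numeric vector of the measure by group (>= 2 finite
#'   values).
#' @param order Tie-break order of group labels; defaults to the fixed
#'   race/ethnicity order.
#' @return List with `max_group`, `min_group`, `gap`, and logical `tie`.
#' @examples
#' range_gap(c(NHAPI = 89.8, NHB = 72.1, NHW = 80, H = 82))
#' @export
range_gap <- function(values, order = race_levels()) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 finite values")
  if (is.null(names(values)) || any(names(values) == "")) stop("values must be named by group")
  ord <- match(names(values), order)
  if (anyNA(ord)) ord[is.na(ord)] <- length(order) + rank(names(values)[is.na(ord)])
  values <- values[base::order(ord)]
  tie <- sum(values == max(values)) > 1 || sum(values == min(values)) > 1
  if (tie) message("range_gap: tie among groups; broken by fixed group order")
  list(max_group = names(values)[which.max(values)],
       min_group = names(values)[which.min(values)],
       gap = max(values) - min(values),
       tie = tie)
}

#' Change in a gap between two periods
#'
#' Returns `gap(t1) - gap(t2)` (earlier minus later): positive values mean
#' the gap narrowed over time, negative values that it widened. The reading
#' is attached as attribute `"direction"`.
#'
#' @param gap_t1 Gap in the earlier period.
#' @param gap_t2 Gap in the later period.
#' @return Numeric change, with attribute `direction` equal to `"narrowed"`,
#'   `"widened"`, or `"unchanged"`.
#' @examples
#' trend_change(15.4, 13.3)  # narrowed by 2.1
#' trend_change(10.8, 12.3)  # widened by 1.5
#' @export
trend_change <- function(gap_t1, gap_t2) {
  if (!is.finite(gap_t1) || !is.finite(gap_t2)) stop("both gaps must be finite")
  change <- gap_t1 - gap_t2
  structure(change, direction = if (change > 0) "narrowed" else if (change < 0) "widened" else "unchanged")
}

#' Pearson correlation between two measures across strata
#'
#' Product-moment correlation of paired stratum-level values of two measures
#' (e.g. sd0 and cv0 across all strata and periods).
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs, each with nonzero
#'   variance).
#' @return Pearson r.
#' @export
measure_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in one of the measures")
  stats::cor(x, y)
}

#' Stratum-level inequality report
#'
#' Builds the inequality table from a wide per-stratum results table (one row
#' per race x gender x urbanicity x period, measure columns such as `e0`,
#' `sd0`, `cv0`, `e65`): for every measure and every race-gender-period cell,
#' the metropolitan-vs-nonmetropolitan absolute difference and ratio; and for
#' every gender-urbanicity-period cell, the between-race range gap (rows with
#' `race == "range"`, whose `direction` names the extreme groups).
#'
#' @param results Wide results table (see [run_pipeline()]), with columns
#'   `race_ethnicity, gender, urbanicity, period` plus measure columns. The
#'   urbanicity column must hold the 2-level codes for the metro-nonmetro
#'   rows to be produced.
#' @param measures Character vector of measure column names to report on;
#'   defaults to all of `e*, sd*, cv*` present.
#' @param urbanicity_a,urbanicity_b The comparison pair: `a` is the reference
#'   (numerator / minuend) member.
#' @return Long data frame with columns `measure, period, gender, race,
#'   urbanicity_a, urbanicity_b, absolute, ratio, direction`.
#' @export
inequality_report <- function(results, measures = NULL,
                              urbanicity_a = "metropolitan",
                              urbanicity_b = "nonmetropolitan") {
  stopifnot(is.data.frame(results),
            all(c("race_ethnicity", "gender", "urbanicity", "period") %in% names(results)))
  if (is.null(measures)) {
    measures <- grep("^(e|sd|cv)[0-9]+$", names(results), value = TRUE)
  }
  if (length(measures) == 0) stop("no measure columns found in results")
  rows <- list()
  ri <- 0L
  add <- function(row) {
    ri <<- ri + 1L
    rows[[ri]] <<- row
  }
  cells <- unique(results[c("period", "gender")])
  for (ci in seq_len(nrow(cells))) {
    per <- cells$period[ci]; gen <- cells$gender[ci]
    sub <- results[results$period == per & results$gender == gen, , drop = FALSE]
    for (m in measures) {
      # metro vs nonmetro within each race
      for (race in unique(sub$race_ethnicity)) {
        va <- sub[[m]][sub$race_ethnicity == race & sub$urbanicity == urbanicity_a]
        vb <- sub[[m]][sub$race_ethnicity == race & sub$urbanicity == urbanicity_b]
        if (length(va) == 1 && length(vb) == 1 && is.finite(va) && is.finite(vb)) {
          add(data.frame(measure = m, period = per, gender = gen, race = race,
                         urbanicity_a = urbanicity_a, urbanicity_b = urbanicity_b,
                         absolute = absolute_gap(va, vb),
                         ratio = relative_ratio(va, vb),
                         direction = if (va > vb) "higher_a" else if (va < vb) "higher_b" else "equal",
                         stringsAsFactors = FALSE))
        }
      }
      # between-race range within each urbanicity level
      for (u in unique(sub$urbanicity)) {
        su <- sub[sub$urbanicity == u & sub$race_ethnicity %in% race_levels(), , drop = FALSE]
        vals <- stats::setNames(su[[m]], su$race_ethnicity)
        vals <- vals[is.finite(vals)]
        if (length(vals) >= 2) {
          rg <- range_gap(vals)
          add(data.frame(measure = m, period = per, gender = gen, race = "range",
                         urbanicity_a = u, urbanicity_b = u,
                         absolute = rg$gap,
                         ratio = relative_ratio(vals[[rg$max_group]], vals[[rg$min_group]]),
                         direction = paste0(rg$max_group, ">", rg$min_group),
                         stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (ri == 0L) stop("no comparable strata found in results")
  out <- do.call(rbind, rows)
  out <- out[order(out$measure, out$period, out$gender, out$race), ]
  rownames(out) <- NULL
  out
}
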