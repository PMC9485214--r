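#' Separation factors (a_x) for the abridged grid
#'
#' Average years lived within each interval by those dying in it. Defaults:
#' `a_0 = 0.1` year for the infant interval (deaths are heavily front-loaded;
#' an Andreev-Kingkade-style rate-dependent rule is available via
#' `infant_rule = "mx"`), 1.5 years for `[1,5)`, the midpoint `n/2` for the
#' interior 5-year intervals, and `1/m` for the open interval (constant-hazard
#' closure, so that `e_85 = 1/m_85+`).
#'
#' @param mx Central death rates aligned to `grid` (needed for the open
#'   interval and the `"mx"` infant rule).
#' @param grid Age grid from [age_grid()].
#' @param a0 Infant separation factor in years (used when
#'   `infant_rule = "fixed"`).
#' @param infant_rule `"fixed"` (default) or `"mx"`, a rate-dependent infant
#'   rule with the Andreev-Kingkade total-population coefficients.
#' @return Numeric vector of separation factors (years).
#' @export
default_ax <- function(mx, grid = age_grid(), a0 = 0.1,
                       infant_rule = c("fixed", "mx")) {
  infant_rule <- match.arg(infant_rule)
  if (length(mx) != nrow(grid)) stop("mx must have one rate per grid interval")
  open <- !is.finite(grid$width)
  if (mx[open] <= 0) stop("closure error: open-interval death rate must be positive")
  ax <- grid$width / 2
  ax[grid$age_start == 1] <- 1.5
  ax[1] <- if (infant_rule == "fixed") {
    a0
  } else if (mx[1] < 0.02) {
    0.14916 - 2.02536 * mx[1]
  } else if (mx[1] < 0.07) {
    0.037495 + 3.57055 * mx[1]
  } else {
    0.28743
  }
  ax[open] <- 1 / mx[open]
  if (any(ax[!open] <= 0) || any(ax[!open] > grid$width[!open])) {
    stop("separation factors must satisfy 0 < a_x <= n for closed intervals")
  }
  ax
}

#' Convert central death rates to death probabilities
#'
#' The standard Greville/Chiang conversion
#' `q_x = n m_x / (1 + (n - a_x) m_x)`, clipped to at most 1; the open
#' interval gets `q = 1`.
#'
#' @param mx Central death rate (1/year), nonnegative.
#' @param n Interval width in years (`Inf` for the open interval).
#' @param ax Separation factor in years.
#' @return Probability of dying within the interval for someone alive at its
#'   start.
#' @examples
#' mx_to_qx(0.02, 5, 2.5)  # 0.1 / 1.05
#' @export
mx_to_qx <- function(mx, n, ax) {
  if (any(!is.finite(mx)) || any(mx < 0)) stop("mx must be nonnegative and finite")
  q <- ifelse(is.finite(n), n * mx / (1 + (n - ax) * mx), 1)
  pmin(q, 1)
}

#' Build an abridged period life table
#'
#' Standard abridged life-table recursion from a schedule of central death
#' rates: `l_{x+n} = l_x (1 - q_x)`, `d_x = l_x q_x`,
#' `L_x = n l_{x+n} + a_x d_x` for closed intervals and `L = l/m` for the open
#' interval, then `T_x` by downward accumulation and `e_x = T_x / l_x`.
#' Radix 100,000. No rounding occurs inside the recursion.
#'
#' @param schedule Either a numeric vector of central death rates aligned to
#'   `grid`, or a data frame with an `mx` column (e.g. from
#'   [schedule_from_siler()] or one stratum of [compute_rates()] output).
#' @param grid Age grid from [age_grid()].
#' @param ax Optional separation factors; defaults to
#'   [default_ax()] with the given `a0`/`infant_rule`.
#' @param a0,infant_rule Passed to [default_ax()].
#' @param radix Starting cohort size `l_0`.
#' @return A `life_table` data frame with columns `age_start, n, mx, ax, qx,
#'   lx, dx, Lx, Tx, ex`.
#' @examples
#' lt <- build_life_table(rep(0.02, 19))
#' lt$ex[1]  # close to 50 (exponential mean 1/0.02)
#' @export
build_life_table <- function(schedule, grid = age_grid(), ax = NULL, a0 = 0.1,
                             infant_rule = "fixed", radix = 1e5) {
  mx <- if (is.data.frame(schedule)) schedule$mx else schedule
  if (is.null(mx)) stop("schedule must be a numeric vector or a data frame with an mx column")
  if (length(mx) != nrow(grid)) stop("schedule must supply one rate per grid interval")
  if (any(!is.finite(mx)) || any(mx < 0)) stop("input error: mx must be nonnegative and finite")
  n <- grid$width
  open <- !is.finite(n)
  if (mx[open] <= 0) stop("closure error: open-interval death rate must be positive")
  if (is.null(ax)) ax <- default_ax(mx, grid, a0 = a0, infant_rule = infant_rule)
  qx <- mx_to_qx(mx, n, ax)
  k <- length(mx)
  lx <- radix * cumprod(c(1, 1 - qx[-k]))
  dx <- lx * qx
  Lx <- ifelse(open, lx / mx, n * c(lx[-1], 0) + ax * dx)
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)
  out <- data.frame(age_start = grid$age_start, n = n, mx = mx, ax = ax,
                    qx = qx, lx = lx, dx = dx, Lx = Lx, Tx = Tx, ex = ex)
  class(out) <- c("life_table", "data.frame")
  out
}

#' Life expectancy at a grid age
#'
#' @param table A `life_table` from [build_life_table()].
#' @param age A start age of the abridged grid (no interpolation is done;
#'   other ages are an error).
#' @return Remaining life expectancy `e_x` in years.
#' @export
life_expectancy_at <- function(table, age) {
  stopifnot(inherits(table, "life_table"))
  table$ex[match_table_age(table, age)]
}

# Shared age lookup with a life-table-specific error message.
match_table_age <- function(table, age) {
  if (length(age) != 1L || !is.finite(age)) stop("age must be a single finite number")
  i <- match(age, table$age_start)
  if (is.na(i)) {
    stop("age ", age, " is not a start age of this life table's grid (no interpolation); ",
         "valid ages: ", paste(table$age_start, collapse = ", "))
  }
  i
}

#' Write or read life tables as CSV
#'
#' @param table A `life_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(table, path) {
  stopifnot(inherits(table, "life_table"))
  out <- table
  names(out) <- c("age_start", "n", "mx", "ax", "qx", "lx", "dx", "Lx", "Tx", "ex")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
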