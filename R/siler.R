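#' Siler mortality model parameters
#'
#' The Siler hazard is the sum of a declining infant component, a constant
#' background component, and an exponentially rising (Gompertz) senescent
#' component:
#' \deqn{h(t) = a_1 e^{-b_1 t} + c + a_2 e^{b_2 t}.}
#' It reproduces the infant-mortality hump plus old-age growth the abridged
#' age grid is designed around, which is why it drives the synthetic
#' vital-registration generator.
#'
#' @param a1 Infant hazard scale (1/year).
#' @param b1 Infant hazard decay rate (1/year).
#' @param c Age-independent background hazard (1/year).
#' @param a2 Senescent hazard scale (1/year).
#' @param b2 Senescent hazard growth rate (1/year).
#' @return An object of class `siler_params`.
#' @examples
#' siler_params(a1 = 0.01, b1 = 1.5, c = 6e-4, a2 = 2e-5, b2 = 0.105)
#' @export
siler_params <- function(a1 = 0.01, b1 = 1.5, c = 6e-4, a2 = 2e-5, b2 = 0.105) {
  p <- list(a1 = a1, b1 = b1, c = c, a2 = a2, b2 = b2)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (length(v) != 1L || !is.finite(v) || v < 0) {
      stop("siler parameter '", nm, "' must be a single nonnegative finite number")
    }
  }
  structure(p, class = "siler_params")
}

#' @export
print.siler_params <- function(x, ...) {
  cat(sprintf("Siler hazard: %.4g*exp(-%.4g t) + %.4g + %.4g*exp(%.4g t)\n",
              x$a1, x$b1, x$c, x$a2, x$b2))
  invisible(x)
}

# A schedule has a finite mean lifetime only if mortality does not vanish at
# old ages.
assert_proper <- function(params) {
  if (params$c <= 0 && params$a2 <= 0) {
    stop("improper Siler schedule: need c > 0 or a2 > 0 for a finite lifespan distribution")
  }
  invisible(params)
}

#' Evaluate the Siler hazard
#'
#' @param params A [siler_params()] object.
#' @param age Vector of ages in years (all must be >= 0).
#' @return Hazard values (1/year), same length as `age`.
#' @examples
#' siler_hazard(siler_params(a1 = 0, b1 = 1, c = 0.02, a2 = 0, b2 = 0.1), 30)
#' @export
siler_hazard <- function(params, age) {
  stopifnot(inherits(params, "siler_params"))
  if (any(!is.finite(age)) || any(age < 0)) stop("age must be nonnegative and finite")
  params$a1 * exp(-params$b1 * age) + params$c + params$a2 * exp(params$b2 * age)
}

#' Cumulative Siler hazard and survival
#'
#' Closed-form integral of the Siler hazard from 0 to `age`, and the implied
#' survival function `exp(-H(age))`.
#'
#' @inheritParams siler_hazard
#' @return Cumulative hazard (dimensionless) or survival probability.
#' @export
siler_cumhaz <- function(params, age) {
  stopifnot(inherits(params, "siler_params"))
  if (any(!is.finite(age)) || any(age < 0)) stop("age must be nonnegative and finite")
  infant <- if (params$b1 > 0) params$a1 / params$b1 * (1 - exp(-params$b1 * age)) else params$a1 * age
  senesc <- if (params$b2 > 0) params$a2 / params$b2 * (exp(params$b2 * age) - 1) else params$a2 * age
  infant + params$c * age + senesc
}

#' @rdname siler_cumhaz
#' @export
siler_survival <- function(params, age) exp(-siler_cumhaz(params, age))

#' Scale a Siler hazard by a proportional-hazards multiplier
#'
#' Multiplies the three scale parameters (`a1`, `c`, `a2`) by `k`, leaving
#' the shape parameters untouched, so the hazard at every age is exactly
#' `k` times the original.
#'
#' @inheritParams siler_hazard
#' @param k Positive multiplier (dimensionless).
#' @export
scale_hazard <- function(params, k) {
  stopifnot(inherits(params, "siler_params"))
  if (length(k) != 1L || !is.finite(k) || k <= 0) stop("multiplier k must be a single positive number")
  siler_params(a1 = params$a1 * k, b1 = params$b1, c = params$c * k,
               a2 = params$a2 * k, b2 = params$b2)
}

# Age beyond which unconditional survival drops under `tail`; used as the
# integration cutoff for the open-ended interval.
lifespan_cutoff <- function(params, tail = 1e-10) {
  assert_proper(params)
  target <- -log(tail)
  hi <- 110
  while (siler_cumhaz(params, hi) < target) hi <- hi * 1.5
  stats::uniroot(function(t) siler_cumhaz(params, t) - target,
                 lower = 0, upper = hi, tol = 1e-6)$root
}

#' Abridged central death rates implied by a Siler hazard
#'
#' Converts a continuous hazard into the central death rate of each interval
#' of the abridged grid,
#' \eqn{m_x = \int h(t) S(t) dt / \int S(t) dt} over the interval, evaluated
#' with fine-step numerical integration (the numerator is taken exactly as
#' the survival drop across the interval). The open interval is integrated
#' to a cutoff where unconditional survival falls below `1e-10`.
#'
#' @inheritParams siler_hazard
#' @param grid Age grid from [age_grid()].
#' @param step Integration step in years (must be positive; default 0.005,
#'   and never coarser than 0.01).
#' @return A mortality schedule: data frame with columns `age_group`,
#'   `age_start`, `width`, `mx` (1/year).
#' @examples
#' schedule_from_siler(siler_params(a1 = 0, b1 = 1, c = 0.02, a2 = 0, b2 = 0.1))
#' @export
schedule_from_siler <- function(params, grid = age_grid(), step = 0.005) {
  stopifnot(inherits(params, "siler_params"))
  if (length(step) != 1L || !is.finite(step) || step <= 0) {
    stop("integration step must be a single positive number")
  }
  if (step > 0.01) stop("integration step must be <= 0.01 year")
  assert_proper(params)
  cutoff <- lifespan_cutoff(params)
  k <- nrow(grid)
  mx <- numeric(k)
  for (i in seq_len(k)) {
    lo <- grid$age_start[i]
    hi <- if (is.finite(grid$width[i])) lo + grid$width[i] else max(cutoff, lo + 1)
    t <- fine_grid(lo, hi, step)
    s <- siler_survival(params, t)
    person_years <- sum(s * trapezoid_weights(t))
    deaths <- s[1] - s[length(s)]
    mx[i] <- deaths / person_years
  }
  out <- grid
  out$mx <- mx
  out
}

#' Exact life expectancy and lifespan variation of a Siler schedule
#'
#' Ground-truth remaining life expectancy `ex`, standard deviation of age at
#' death among survivors (`sdx`), and coefficient of variation
#' (`cvx = sdx / ex`) at the requested starting ages, obtained by fine-step
#' numerical integration of the continuous survival curve (no age grouping).
#'
#' @inheritParams siler_hazard
#' @param ages Starting ages (years) at which to evaluate.
#' @param step Integration step in years.
#' @return Data frame with columns `age`, `ex`, `sdx`, `cvx`.
#' @examples
#' siler_truth(siler_params(a1 = 0, b1 = 1, c = 0.02, a2 = 0, b2 = 0.1))
#' @export
siler_truth <- function(params, ages = 0, step = 0.01) {
  stopifnot(inherits(params, "siler_params"))
  if (any(!is.finite(ages)) || any(ages < 0)) stop("ages must be nonnegative and finite")
  assert_proper(params)
  cutoff <- lifespan_cutoff(params)
  rows <- lapply(ages, function(y) {
    t <- fine_grid(y, max(cutoff, y + 1), step)
    s <- siler_survival(params, t) / siler_survival(params, y)
    w <- trapezoid_weights(t)
    e <- sum(s * w)
    m2 <- 2 * sum((t - y) * s * w)
    v <- max(m2 - e^2, 0)
    data.frame(age = y, ex = e, sdx = sqrt(v), cvx = sqrt(v) / e)
  })
  do.call(rbind, rows)
}

#' Simulate exact individual lifetimes from a Siler hazard
#'
#' Draws ages at death by inverting the closed-form cumulative hazard against
#' unit-exponential deviates (interpolated on a fine grid). Used as an
#' independent brute-force oracle for the life-table and variation modules.
#'
#' @inheritParams siler_hazard
#' @param n Number of lifetimes.
#' @param seed RNG seed.
#' @param step Grid step (years) for the inversion table.
#' @return Numeric vector of `n` ages at death (years).
#' @export
simulate_lifetimes <- function(params, n, seed, step = 0.01) {
  stopifnot(inherits(params, "siler_params"))
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("n must be a positive count")
  assert_proper(params)
  cutoff <- lifespan_cutoff(params)
  t <- fine_grid(0, cutoff, step)
  H <- siler_cumhaz(params, t)
  u <- with_seed(seed, stats::rexp(n))
  stats::approx(H, t, xout = pmin(u, max(H)), ties = "ordered")$y
}

#' Simulate stratified death counts from a mortality schedule
#'
#' Draws per-interval death counts `D_x ~ Poisson(m_x * N_x)` given a
#' mortality schedule and person-years of exposure.
#'
#' @param schedule A mortality schedule (data frame with `age_start`, `width`,
#'   `mx`), e.g. from [schedule_from_siler()].
#' @param exposures Person-years per interval (same length as the schedule,
#'   all nonnegative).
#' @param seed RNG seed.
#' @return Vital counts: data frame with columns `age_group`, `age_start`,
#'   `width`, `deaths`, `person_years`.
#' @export
simulate_counts <- function(schedule, exposures, seed) {
  stopifnot(is.data.frame(schedule), all(c("age_start", "width", "mx") %in% names(schedule)))
  if (length(exposures) != nrow(schedule)) {
    stop("exposures must have one value per schedule interval")
  }
  if (any(!is.finite(exposures)) || any(exposures < 0)) {
    stop("exposures must be nonnegative and finite")
  }
  if (any(!is.finite(schedule$mx)) || any(schedule$mx < 0)) {
    stop("schedule mx must be nonnegative and finite")
  }
  deaths <- with_seed(seed, stats::rpois(nrow(schedule), schedule$mx * exposures))
  out <- data.frame(age_group = if ("age_group" %in% names(schedule)) schedule$age_group else age_labels(),
                    age_start = schedule$age_start, width = schedule$width,
                    deaths = deaths, person_years = exposures,
                    stringsAsFactors = FALSE)
  out
}
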