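#' Abridged age grid used throughout the package
#'
#' The standard NCHS-style abridged partition of age: infancy `[0,1)`, early
#' childhood `[1,5)`, then 5-year intervals up to `[80,85)`, and an open-ended
#' terminal interval `85+`. All life tables, schedules, and count files in
#' this package are aligned to this 19-interval grid.
#'
#' @return A data frame with one row per interval and columns `age_group`
#'   (label, e.g. `"1-4"`, `"85+"`), `age_start` (exact start age in years),
#'   and `width` (interval width in years; `Inf` for the open interval).
#' @examples
#' age_grid()
#' @export
age_grid <- function() {
  starts <- c(0, 1, seq(5, 85, by = 5))
  widths <- c(1, 4, rep(5, 16), Inf)
  labels <- c("0", "1-4",
              paste(seq(5, 80, by = 5), seq(9, 84, by = 5), sep = "-"),
              "85+")
  data.frame(age_group = labels, age_start = starts, width = widths,
             stringsAsFactors = FALSE)
}

# Fixed vocabularies for the stratification variables.
age_labels <- function() age_grid()$age_group
race_levels <- function() c("H", "NHW", "NHB", "NHAPI")
gender_levels <- function() c("man", "woman")
urbanicity6_levels <- function() {
  c("large_central", "large_fringe", "medium", "small", "micropolitan", "noncore")
}
urbanicity2_levels <- function() c("metropolitan", "nonmetropolitan")

# Map 6-level codes to the 2-level metro/nonmetro dichotomy.
urbanicity6_to_2 <- function(codes) {
  metro <- c("large_central", "large_fringe", "medium", "small")
  bad <- setdiff(unique(codes), urbanicity6_levels())
  if (length(bad) > 0) {
    stop("unknown 6-level urbanicity code(s): ", paste(bad, collapse = ", "))
  }
  ifelse(codes %in% metro, "metropolitan", "nonmetropolitan")
}
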