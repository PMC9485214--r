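tiny_counts <- function() {
  grid <- expand.grid(year = 1990L, county_fips = c("22001", "22002", "01001"),
                      age_group = age_grid()$age_group, gender = "man",
                      race_ethnicity = c("H", "NHW"), stringsAsFactors = FALSE)
  grid$deaths <- 2L
  grid$population <- 1000L
  validate_counts(grid)
}

test_that("counts validation enforces vocabulary and cell uniqueness", {
  x <- tiny_counts()
  expect_s3_class(validate_counts(x), "data.frame")
  bad <- x; bad$age_group[1] <- "85plus"
  expect_error(validate_counts(bad), "unknown age group")
  dup <- rbind(x, x[1, ])
  expect_error(validate_counts(dup), "duplicated cell")
  neg <- x; neg$deaths[3] <- -1L
  expect_error(validate_counts(neg), "nonnegative")
  orphan <- x; orphan$population[2] <- 0L
  expect_error(validate_counts(orphan), "zero population")
})

test_that("county merges sum cells and conserve totals", {
  x <- tiny_counts()
  expect_identical(apply_county_merges(x, NULL), x)
  merges <- data.frame(old_fips = "22002", new_fips = "22001")
  m <- apply_county_merges(x, merges)
  expect_false("22002" %in% m$county_fips)
  expect_equal(sum(m$deaths), sum(x$deaths))
  expect_equal(sum(m$population), sum(x$population))
  one <- m[m$county_fips == "22001" & m$age_group == "0" & m$race_ethnicity == "H", ]
  expect_equal(one$deaths, 4L)  # two identical counties collapsed
  expect_equal(one$population, 2000L)
})

test_that("exclusions remove exactly the matching state-year-race rows", {
  x <- rbind(tiny_counts(),
             transform(tiny_counts(), year = 1991L))
  expect_message(out <- apply_exclusions(x, default_exclusions()), "person-years")
  # Louisiana (22) Hispanic rows are dropped for 1990 only
  expect_false(any(out$year == 1990 & substr(out$county_fips, 1, 2) == "22" &
                     out$race_ethnicity == "H"))
  expect_true(any(out$year == 1991 & substr(out$county_fips, 1, 2) == "22" &
                    out$race_ethnicity == "H"))
  # non-Hispanic and other-state rows are untouched
  expect_equal(sum(out$race_ethnicity == "NHW"), sum(x$race_ethnicity == "NHW"))
  expect_true(all(out$county_fips != "" & substr(out$county_fips, 1, 2) != "22" |
                    out$race_ethnicity != "H" | out$year != 1990))
  got <- attr(out, "excluded")
  expect_equal(got$person_years, sum(x$population[x$year == 1990 &
                                                    substr(x$county_fips, 1, 2) == "22" &
                                                    x$race_ethnicity == "H"]))
})

test_that("the default exclusions are a no-op without matching states", {
  x <- tiny_counts()
  x$county_fips <- sub("^22", "06", x$county_fips)
  expect_message(out <- apply_exclusions(x, default_exclusions()))
  expect_equal(nrow(out), nrow(x))
})

test_that("the national fixture loses under 1% of Hispanic person-years to exclusions", {
  b <- national_fixture()$bundle
  suppressMessages(out <- apply_exclusions(b$counts, default_exclusions()))
  frac <- attr(out, "excluded")$fraction_of_race_py
  expect_gt(frac, 0)
  expect_lt(frac, 0.01)
})

test_that("urbanicity mapping collapses 6 levels into metro/nonmetro", {
  x <- tiny_counts()
  xw <- data.frame(county_fips = c("22001", "22002", "01001"),
                   urbanicity6 = c("noncore", "medium", "large_central"))
  two <- map_urbanicity(x, xw, levels = 2)
  expect_equal(unique(two$urbanicity[two$county_fips == "22001"]), "nonmetropolitan")
  expect_equal(unique(two$urbanicity[two$county_fips == "22002"]), "metropolitan")
  six <- map_urbanicity(x, xw, levels = 6)
  expect_equal(sort(unique(six$urbanicity)), sort(unique(xw$urbanicity6)))
  expect_error(map_urbanicity(x, xw[-1, ], levels = 2), "missing from crosswalk")
  expect_error(map_urbanicity(x, xw, levels = 3), "2 or 6")
})

test_that("period pooling is additive and rejects uncovered years", {
  x <- tiny_counts()
  xw <- data.frame(county_fips = unique(x$county_fips),
                   urbanicity6 = c("noncore", "medium", "large_central"))
  x2 <- map_urbanicity(x, xw, levels = 2)
  one <- pool_and_aggregate(x2)
  five <- pool_and_aggregate(
    do.call(rbind, lapply(1990:1994, function(y) transform(x2, year = y))))
  m <- merge(one, five, by = c("race_ethnicity", "gender", "urbanicity", "period", "age_group"))
  expect_equal(m$deaths.y, 5 * m$deaths.x)
  expect_equal(m$person_years.y, 5 * m$person_years.x)
  expect_equal(sum(one$deaths), sum(x2$deaths))  # conservation
  bad <- transform(x2, year = 1985L)
  expect_error(pool_and_aggregate(bad), "outside all periods")
})

test_that("aggregating at 6 levels then collapsing equals the 2-level aggregation", {
  b <- national_fixture()$bundle
  six <- pool_and_aggregate(map_urbanicity(b$counts, b$crosswalk, levels = 6))
  six$urbanicity <- urbanicity6_to_2(six$urbanicity)
  collapsed <- stats::aggregate(six[c("deaths", "person_years")],
                                six[c("race_ethnicity", "gender", "urbanicity",
                                      "period", "age_group")], FUN = sum)
  two <- pool_and_aggregate(map_urbanicity(b$counts, b$crosswalk, levels = 2))
  m <- merge(two, collapsed,
             by = c("race_ethnicity", "gender", "urbanicity", "period", "age_group"))
  expect_equal(nrow(m), nrow(two))
  expect_equal(m$deaths.x, m$deaths.y)
  expect_equal(m$person_years.x, m$person_years.y)
})

test_that("pooled totals preserve the generator's counts exactly", {
  b <- national_fixture()$bundle
  vital <- pool_and_aggregate(map_urbanicity(b$counts, b$crosswalk, levels = 2))
  expect_equal(sum(vital$deaths), sum(b$counts$deaths))
  expect_equal(sum(vital$person_years), sum(b$counts$population))
})

test_that("compute_rates divides deaths by exposure and flags unusable strata", {
  x <- tiny_counts()
  xw <- data.frame(county_fips = unique(x$county_fips),
                   urbanicity6 = c("noncore", "medium", "large_central"))
  vital <- pool_and_aggregate(map_urbanicity(x, xw, levels = 2))
  rates <- compute_rates(vital)
  expect_equal(unique(rates$mx), (2 * 2) / (2 * 1000))  # metro: two counties pooled
  # a zero open-interval count makes the stratum unusable
  broken <- vital
  broken$deaths[!is.finite(broken$width) & broken$urbanicity == "nonmetropolitan"] <- 0L
  expect_warning(kept <- compute_rates(broken), "unusable")
  expect_false("nonmetropolitan" %in% kept$urbanicity)
  expect_match(attr(kept, "dropped"), "nonmetropolitan")
  # zero exposure with deaths is a hard error
  bad <- vital; bad$person_years[1] <- 0
  expect_error(compute_rates(bad), "data error")
})
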