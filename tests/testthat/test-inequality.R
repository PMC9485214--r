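test_that("absolute gaps and ratios reproduce the published worked examples", {
  expect_equal(absolute_gap(89.8, 72.1), 17.7)
  expect_equal(absolute_gap(87.7, 70.8), 16.9)
  expect_equal(absolute_gap(5, 5), 0)
  expect_equal(round(relative_ratio(77.0, 74.5), 2), 1.03)
  expect_equal(round(relative_ratio(82.0, 79.5), 2), 1.03)
  expect_equal(relative_ratio(5, 5), 1)
  expect_error(relative_ratio(1, 0), "positive")
  expect_error(absolute_gap(NA, 1), "finite")
})

test_that("gap sign and ratio direction always agree", {
  set.seed(51)
  a <- runif(50, 60, 90)
  b <- runif(50, 60, 90)
  expect_equal(absolute_gap(a, b) > 0, relative_ratio(a, b) > 1)
})

test_that("range_gap finds the extremes and equals brute-force max minus min", {
  rg <- range_gap(c(NHAPI = 89.8, NHB = 72.1, NHW = 80.2, H = 82.5))
  expect_equal(rg$max_group, "NHAPI")
  expect_equal(rg$min_group, "NHB")
  expect_equal(rg$gap, 17.7)
  expect_false(rg$tie)
  set.seed(52)
  for (i in 1:20) {
    v <- stats::setNames(runif(4, 60, 90), race_levels())
    rg <- range_gap(v)
    expect_equal(rg$gap, max(v) - min(v))
    expect_equal(v[[rg$max_group]], max(v))
    expect_equal(v[[rg$min_group]], min(v))
  }
})

test_that("range_gap ties break by the fixed race order and are flagged", {
  expect_message(rg <- range_gap(c(NHB = 70, H = 70, NHW = 70, NHAPI = 70)), "tie")
  expect_equal(rg$gap, 0)
  expect_true(rg$tie)
  expect_equal(rg$max_group, "H")  # first in fixed order
  expect_error(range_gap(c(a = 1)), "at least 2")
})

test_that("trend_change reports narrowing and widening with the stated sign", {
  narrowed <- trend_change(15.4, 13.3)
  expect_equal(as.numeric(narrowed), 2.1)
  expect_equal(attr(narrowed, "direction"), "narrowed")
  widened <- trend_change(10.8, 12.3)
  expect_equal(as.numeric(widened), -1.5)
  expect_equal(attr(widened, "direction"), "widened")
  expect_equal(attr(trend_change(3, 3), "direction"), "unchanged")
})

test_that("measure_correlation is the Pearson product-moment coefficient", {
  x <- 1:10
  expect_equal(measure_correlation(x, 2 * x + 1), 1)
  expect_equal(measure_correlation(x, -x), -1)
  set.seed(53)
  sd0 <- runif(20, 10, 20)
  cv0 <- 0.01 * sd0 + rnorm(20, 0, 0.005)
  # from-scratch covariance / variance computation as the oracle
  r_oracle <- sum((sd0 - mean(sd0)) * (cv0 - mean(cv0))) /
    sqrt(sum((sd0 - mean(sd0))^2) * sum((cv0 - mean(cv0))^2))
  expect_equal(measure_correlation(sd0, cv0), r_oracle, tolerance = 1e-12)
  expect_error(measure_correlation(1:2, 2:3), "at least 3")
  expect_error(measure_correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("inequality_report lays out metro-nonmetro and range rows", {
  results <- expand.grid(race_ethnicity = c(race_levels(), "ALL"),
                         gender = gender_levels(),
                         urbanicity = urbanicity2_levels(),
                         period = "2015-2019", stringsAsFactors = FALSE)
  set.seed(54)
  results$e0 <- runif(nrow(results), 70, 90)
  rep <- inequality_report(results, measures = "e0")
  metro <- rep[rep$race != "range", ]
  expect_equal(nrow(metro), 5 * 2)  # 4 races + ALL, per gender
  for (i in seq_len(nrow(metro))) {
    a <- results$e0[results$race_ethnicity == metro$race[i] &
                      results$gender == metro$gender[i] &
                      results$urbanicity == "metropolitan"]
    b <- results$e0[results$race_ethnicity == metro$race[i] &
                      results$gender == metro$gender[i] &
                      results$urbanicity == "nonmetropolitan"]
    expect_equal(metro$absolute[i], a - b)
    expect_equal(metro$ratio[i], a / b)
  }
  ranges <- rep[rep$race == "range", ]
  expect_equal(nrow(ranges), 2 * 2)  # per gender x urbanicity, races only
  expect_true(all(ranges$absolute >= 0))
  expect_error(inequality_report(results[0, ]), "no comparable strata")
})
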