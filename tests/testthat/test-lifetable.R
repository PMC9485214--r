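test_that("separation factors follow the stated rules", {
  mx <- rep(0.02, 19)
  mx[19] <- 0.125
  ax <- default_ax(mx)
  grid <- age_grid()
  expect_equal(ax[grid$age_start == 30], 2.5)   # interior midpoint
  expect_equal(ax[grid$age_start == 1], 1.5)
  expect_equal(ax[1], 0.1)                      # fixed infant default
  expect_equal(ax[19], 8)                       # 1/m closure
  expect_error(default_ax(rep(0, 19)), "closure error")
  # the rate-dependent infant rule responds to m0
  low <- default_ax(mx, infant_rule = "mx")
  expect_lt(low[1], 0.15)
  hi <- mx; hi[1] <- 0.1
  expect_equal(default_ax(hi, infant_rule = "mx")[1], 0.28743)
})

test_that("mx_to_qx applies the Greville conversion with clipping", {
  expect_equal(mx_to_qx(0, 5, 2.5), 0)
  expect_equal(mx_to_qx(0.02, 5, 2.5), 0.1 / 1.05)
  expect_equal(mx_to_qx(10, 5, 2.5), 1)     # clipped
  expect_equal(mx_to_qx(0.5, Inf, 2), 1)    # open interval
  expect_error(mx_to_qx(-0.1, 5, 2.5), "nonnegative")
})

test_that("constant hazard reproduces the exponential oracle", {
  lt <- build_life_table(rep(0.02, 19))
  expect_equal(lt$ex[1], 50, tolerance = 0.5 / 50)
  expect_equal(life_expectancy_at(lt, 65), 50, tolerance = 0.5 / 50)
  expect_equal(lt$ex[19], 50)  # exact under constant-hazard closure
})

test_that("life-table accounting identities hold for random schedules", {
  set.seed(31)
  for (i in 1:10) {
    lt <- build_life_table(schedule_from_siler(random_siler()))
    expect_equal(sum(lt$dx), lt$lx[1], tolerance = 1e-6)
    # mean age at death equals e0 under the person-years accounting
    expect_equal(sum(lt$dx * (lt$age_start + lt$ax)) / lt$lx[1], lt$ex[1],
                 tolerance = 1e-9)
    expect_true(all(diff(lt$lx) <= 0))
    expect_true(all(lt$qx >= 0 & lt$qx <= 1))
    # every column finite apart from the open interval's width
    expect_true(all(is.finite(as.matrix(lt[setdiff(names(lt), "n")]))))
    expect_true(all(is.finite(lt$n[-19])))
  }
})

test_that("abridged e0 tracks fine-grid integration of the same hazard", {
  set.seed(32)
  for (i in 1:5) {
    p <- random_siler()
    lt <- build_life_table(schedule_from_siler(p))
    expect_equal(lt$ex[1], siler_truth(p)$ex, tolerance = 0.01)
  }
})

test_that("e_x responds only to mortality at or above x", {
  sch <- schedule_from_siler(siler_params())$mx
  lt <- build_life_table(sch)
  doubled <- build_life_table(2 * sch)
  expect_lt(doubled$ex[1], lt$ex[1])
  # raising one rate above x lowers e_x ...
  bump <- sch; bump[age_grid()$age_start == 50] <- bump[age_grid()$age_start == 50] * 2
  expect_lt(life_expectancy_at(build_life_table(bump), 35),
            life_expectancy_at(lt, 35))
  # ... while rates strictly below x leave e_x untouched
  bump_young <- sch; bump_young[2] <- bump_young[2] * 5
  expect_equal(life_expectancy_at(build_life_table(bump_young), 35),
               life_expectancy_at(lt, 35))
})

test_that("life_expectancy_at rejects off-grid ages", {
  lt <- build_life_table(rep(0.02, 19))
  expect_equal(life_expectancy_at(lt, 0), lt$ex[1])
  expect_error(life_expectancy_at(lt, 87), "not a start age")
})

test_that("life tables reject invalid schedules", {
  expect_error(build_life_table(c(rep(0.01, 18), 0)), "closure")
  expect_error(build_life_table(rep(NA_real_, 19)), "input error")
  expect_error(build_life_table(rep(0.01, 10)), "one rate per grid interval")
})

test_that("life tables round-trip through CSV with exact column names", {
  lt <- build_life_table(rep(0.02, 19))
  path <- tempfile(fileext = ".csv")
  write_life_table(lt, path)
  back <- utils::read.csv(path)
  expect_identical(names(back),
                   c("age_start", "n", "mx", "ax", "qx", "lx", "dx", "Lx", "Tx", "ex"))
  expect_equal(back$ex, lt$ex)
})
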