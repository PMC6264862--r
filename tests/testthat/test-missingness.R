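test_that("recorded-day counts ignore all-missing rows", {
  d10 <- make_diary(matrix(0L, 10, 2))
  expect_equal(unname(length_distribution(list(d10))$counts), 10)

  d20 <- blank_days(make_diary(matrix(1L, 20, 2)),
                    as.Date("2020-01-03") + 0:4)
  expect_equal(unname(length_distribution(list(d20))$counts), 15)

  sim <- simulate_cohort(cohort_config(n_children = 5, base_hazard = 0,
                                       spike_hazard = 0, gap_rate = 0,
                                       seed = 2))
  ld <- length_distribution(sim$diaries)
  expect_true(all(ld$counts == 1096))
  expect_equal(ld$summary$frac_full, 1)
  expect_error(length_distribution(list()), "empty cohort")
})

test_that("missingness-by-age curve reflects dropout and gaps", {
  clean <- make_diary(matrix(0L, 600, 2), child_id = "a")
  expect_true(all(missing_fraction_by_age(list(clean))$prop_missing == 0))

  short <- make_diary(matrix(0L, 500, 2), child_id = "b")
  curve <- missing_fraction_by_age(list(clean, short))
  expect_true(all(curve$prop_missing[1:500] == 0))
  expect_true(all(curve$prop_missing[501:600] == 0.5))
})

test_that("hazard spikes appear as jumps in the missingness curve", {
  sim <- cohort_cache("calib1000",
                      cohort_config(n_children = 1000, gap_rate = 0,
                                    seed = 31))
  curve <- missing_fraction_by_age(sim$diaries, max_age = 1096)
  inc <- diff(curve$prop_missing)
  jump_365 <- max(inc[363:366])
  expect_gt(jump_365, 10 * max(stats::median(inc), 1e-5))
})

test_that("burden is the mean over observed cells", {
  zero <- make_diary(matrix(0L, 50, 4))
  expect_equal(burden_vs_length(list(zero))$table$burden, 0)

  v <- matrix(0L, 100, 10)
  v[1:10, 1] <- 1L   # 10 symptom-days over 1000 cells
  one <- make_diary(v)
  expect_equal(burden_vs_length(list(one))$table$burden, 0.01)

  empty <- blank_days(make_diary(matrix(0L, 5, 2), child_id = "gone"),
                      as.Date("2020-01-01") + 0:4)
  expect_warning(res <- burden_vs_length(list(zero, empty)),
                 "zero observed")
  expect_equal(nrow(res$table), 1)
})

test_that("the 15-missing-days boundary decides shape inclusion", {
  base <- full_diary(0L)                      # 36 complete months
  march <- as.Date("2020-03-01") + 0:15

  incl15 <- shape_inclusion(list(blank_days(base, march[1:15])))
  expect_true(incl15$children$shape_included)
  expect_false(incl15$children$complete)

  incl16 <- shape_inclusion(list(blank_days(base, march[1:16])))
  expect_false(incl16$children$shape_included)

  incl0 <- shape_inclusion(list(base))
  expect_true(incl0$children$shape_included)
  expect_true(incl0$children$complete)
})

test_that("pattern years are included prefix-wise", {
  base <- full_diary(0L)
  # third participation year heavily missing: two rows survive
  y3 <- blank_days(base, as.Date("2022-03-01") + 0:24)
  i3 <- pattern_inclusion(list(y3))
  expect_equal(i3$children$pattern_years, 2)
  expect_false(i3$children$shape_included)

  # shape-included diary contributes all three years
  expect_equal(pattern_inclusion(list(base))$children$pattern_years, 3)

  # failure in year one blocks later clean years
  y1 <- blank_days(base, as.Date("2020-03-01") + 0:24)
  expect_equal(pattern_inclusion(list(y1))$children$pattern_years, 0)
})

test_that("removing observed days never rescues an excluded diary", {
  base <- full_diary(0L)
  march <- as.Date("2020-03-01") + 0:30
  excluded <- blank_days(base, march[1:16])
  expect_false(shape_inclusion(list(excluded))$children$shape_included)
  more <- blank_days(excluded, as.Date("2020-05-01") + 0:20)
  expect_false(shape_inclusion(list(more))$children$shape_included)
  expect_lte(pattern_inclusion(list(more))$children$pattern_years,
             pattern_inclusion(list(excluded))$children$pattern_years)
})

test_that("pattern row totals decompose over shape inclusion", {
  sim <- cohort_cache("mixed120",
                      cohort_config(n_children = 120, seed = 8))
  incl <- shape_inclusion(sim$diaries)
  extra <- sum(incl$children$pattern_years[!incl$children$shape_included])
  expect_equal(incl$n_pattern_rows, 3 * incl$n_shape_included + extra)
  expect_true(all(incl$children$pattern_years[
    incl$children$shape_included] == 3))
  expect_true(all(incl$children$shape_included[incl$children$complete]))
  Fm <- suppressWarnings(build_frequency_matrix(sim$diaries,
                                                inclusion = incl))
  expect_equal(nrow(Fm), incl$n_pattern_rows)
})
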