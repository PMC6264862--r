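test_that("degenerate configurations behave exactly as promised", {
  # no onset possible anywhere: all-zero diaries
  cc <- cohort_config(n_children = 5, mu = -Inf, amplitude = 0, p_stay = 0,
                      coupling = 0, base_hazard = 0, spike_hazard = 0,
                      gap_rate = 0, seed = 3)
  sim <- simulate_cohort(cc)
  for (d in sim$diaries) {
    expect_equal(nrow(d), cc$follow_up_days)
    expect_true(all(diary_values(d) == 0L))
  }
  # invalid configs fail fast
  expect_error(cohort_config(n_children = 0), "positive count")
  expect_error(cohort_config(symptoms = character(0)), "empty symptom")
  expect_error(cohort_config(class_proportions = c(a = 0.5, b = 0.4)),
               "sum to 1")
  expect_error(cohort_config(p_stay = 1.2), "\\[0, 1\\]")
})

test_that("simulation is reproducible and emits valid consecutive diaries", {
  cc <- cohort_config(n_children = 6, seed = 99)
  s1 <- simulate_cohort(cc)
  s2 <- simulate_cohort(cc)
  expect_identical(lapply(s1$diaries, diary_values),
                   lapply(s2$diaries, diary_values))
  expect_identical(s1$truth$children, s2$truth$children)
  for (i in seq_along(s1$diaries)) {
    d <- s1$diaries[[i]]
    v <- diary_values(d)
    expect_true(all(v %in% c(0L, 1L, NA)))
    expect_identical(d$date, min(d$date) + seq_len(nrow(d)) - 1)
    expect_lte(s1$truth$children$dropout_day[i], cc$follow_up_days)
    expect_equal(nrow(d), s1$truth$children$dropout_day[i])
  }
})

test_that("empirical cold prevalence tracks the seasonal two-state chain", {
  # single class, coupling off, full observation: the daily cold
  # prevalence must match the periodic fixed point of its own chain
  cc <- cohort_config(
    n_children = 500, symptoms = c("cough", "cold"),
    class_proportions = c(only = 1),
    class_effects = matrix(0, 1, 2, dimnames = list("only", NULL)),
    coupling = 0, base_hazard = 0, spike_hazard = 0, gap_rate = 0,
    follow_up_days = 730, seed = 21)
  sim <- simulate_cohort(cc)
  m_cold <- which(cc$symptoms == "cold")
  oracle_daily <- seasonal_prevalence(cc$mu[m_cold], cc$amplitude[m_cold],
                                      cc$phase[m_cold], cc$p_stay[m_cold])
  month_of_yday <- as.POSIXlt(as.Date("2021-01-01") + 0:364)$mon + 1
  oracle_month <- tapply(oracle_daily, month_of_yday, mean)

  num <- den <- numeric(12)
  for (d in sim$diaries) {
    mon <- as.POSIXlt(d$date)$mon + 1
    cold <- d$cold
    num <- num + tapply(cold, factor(mon, levels = 1:12), sum,
                        default = 0)
    den <- den + tabulate(mon, 12)
  }
  emp_month <- num / den
  expect_lt(max(abs(emp_month - oracle_month)), 0.02)
  # winter-peaked around 0.3, summer trough near 0.05
  expect_gt(emp_month[1], 0.25)
  expect_lt(emp_month[7], 0.08)
})

test_that("dropout is calibrated at age 2.5y and independent of burden", {
  sim <- cohort_cache("calib1000",
                      cohort_config(n_children = 1000, gap_rate = 0,
                                    seed = 31))
  observed_913 <- mean(sim$truth$children$dropout_day >= 913)
  expect_gt(observed_913, 0.87)
  expect_lt(observed_913, 0.93)
  # burden-length correlation: zero in expectation; a single cohort's
  # estimate has Monte-Carlo sd ~0.06 (only ~10% of children have
  # non-full lengths), so the mean over three cohorts carries the
  # sharp bound
  rs <- vapply(c(31, 32, 33), function(sd) {
    s <- if (sd == 31) sim else {
      simulate_cohort(cohort_config(n_children = 1000, gap_rate = 0,
                                    seed = sd))
    }
    suppressWarnings(burden_vs_length(s$diaries))$correlation
  }, numeric(1))
  expect_true(all(abs(rs) < 0.2))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("respiratory coupling inflates cough+cold co-occurrence", {
  count_cc <- function(sim) {
    hits <- days <- 0
    for (d in sim$diaries) {
      v <- diary_values(d)
      obs <- rowSums(is.na(v)) == 0
      hits <- hits + sum(v[obs, "cough"] == 1 & v[obs, "cold"] == 1)
      days <- days + sum(obs)
    }
    hits / days
  }
  base <- list(n_children = 500, follow_up_days = 365, seed = 61,
               base_hazard = 0, spike_hazard = 0, gap_rate = 0)
  on <- count_cc(simulate_cohort(do.call(cohort_config, base)))
  off <- count_cc(simulate_cohort(do.call(cohort_config,
                                          c(base, list(coupling = 0)))))
  expect_gt(on, off)
})
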