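test_that("slot assignment reproduces the cut-and-reposition cascade", {
  # enrolment on 1 January: identity mapping, month k -> (ceil(k/12), k mod 12)
  jan <- full_diary(0L, start = "2020-01-01")
  s <- assign_slots(jan)
  expect_true(all(s$rel_year == rep(1:3, times = c(366, 365, 365))))
  expect_equal(s$slot, (s$rel_year - 1) * 12 + s$cal_month)

  # July enrolment: July y1 -> (1,7); next January -> (1,1); July y2 -> (2,7)
  jul <- full_diary(0L, start = "2020-07-01")
  s <- assign_slots(jul, quiet = TRUE)   # final day starts a 4th July
  pick <- function(date) s[s$date == as.Date(date), c("rel_year", "cal_month")]
  expect_equal(unlist(pick("2020-07-15")), c(rel_year = 1, cal_month = 7))
  expect_equal(unlist(pick("2021-01-15")), c(rel_year = 1, cal_month = 1))
  expect_equal(unlist(pick("2021-07-15")), c(rel_year = 2, cal_month = 7))
})

test_that("every enrolment month yields a collision-free 36-slot grid", {
  for (m in 1:12) {
    start <- as.Date(sprintf("2020-%02d-01", m))
    end <- seq(start, by = "36 months", length.out = 2)[2] - 1
    d <- full_diary(0L, days = as.integer(end - start) + 1,
                    start = as.character(start))
    s <- assign_slots(d)
    expect_false(anyNA(s$rel_year))
    # each of the 36 slots receives exactly one calendar month
    per_slot <- tapply(s$cal_year * 12 + s$cal_month, s$slot,
                       function(k) length(unique(k)))
    expect_length(per_slot, 36)
    expect_true(all(per_slot == 1))
    # repositioning permutes months: the multiset of (year, month) keys
    # is unchanged
    expect_setequal(unique(s$slot), 1:36)
  }
})

test_that("days beyond a third occurrence of a month are dropped", {
  d <- full_diary(0L, days = 1200, start = "2020-01-01")
  expect_warning(s <- assign_slots(d), "beyond relative year")
  expect_true(anyNA(s$rel_year))
  expect_true(all(s$slot[!is.na(s$rel_year)] <= 36))
})

test_that("monthly proportions count observed days only", {
  d <- full_diary(0L, M = 2)
  d$s1[d$date >= "2020-01-01" & d$date <= "2020-01-31"] <- 1L
  p <- monthly_proportions(d)
  expect_equal(unname(p["s1", 1]), 1.0)  # symptom on every day of a full month
  expect_equal(unname(p["s2", 1]), 0.0)  # all-zero month

  # 15 missing days leaves 16 observed; 4 symptom days -> 0.25
  d2 <- full_diary(0L, M = 2)
  d2$s1[d2$date %in% (as.Date("2020-03-01") + 0:3)] <- 1L
  d2 <- blank_days(d2, as.Date("2020-03-17") + 0:14)
  p2 <- monthly_proportions(d2)
  expect_equal(unname(p2["s1", 3]), 4 / 16)

  # 16 missing days: slot undefined
  d3 <- blank_days(full_diary(0L, M = 2), as.Date("2020-03-16") + 0:15)
  expect_warning(p3 <- monthly_proportions(d3), "undefined")
  expect_true(all(is.na(p3[, 3])))
  expect_false(anyNA(p3[, -3]))
})

test_that("tensor stacking and matricization are exact inverses", {
  z <- full_diary(0L, child_id = "z1")
  tn <- build_tensor(list(z))
  expect_equal(dim(tn), c(1, 3, 36))
  expect_true(all(tn == 0))

  twin <- full_diary(1L, child_id = "z2")
  tn2 <- build_tensor(list(twin, full_diary(1L, child_id = "z3")))
  expect_equal(tn2[1, , ], tn2[2, , ])

  set.seed(4)
  A <- array(runif(2 * 3 * 36), dim = c(2, 3, 36),
             dimnames = list(c("a", "b"), c("s1", "s2", "s3"), NULL))
  class(A) <- c("symptom_tensor", "array")
  X <- matricize(A)
  expect_equal(dim(X), c(2, 108))
  # indexing oracle: column (m, t) of the matrix is fibre (., m, t)
  T <- 36
  for (m in 1:3) {
    for (t in c(1, 5, 36)) {
      expect_equal(unname(X[, (m - 1) * T + t]), unname(A[, m, t]))
    }
  }
  back <- unmatricize(X, M = 3, T = 36, dimnames = dimnames(A))
  expect_equal(unclass(back)[, , ], unclass(A)[, , ])
  short <- make_diary(matrix(0L, 30, 3))   # nowhere near 36 months
  expect_error(build_tensor(list(short)), "no shape-included")
})

test_that("aligned seasonal structure survives into the tensor", {
  # children all enrolled on the first of different months, no dropout:
  # the mean cold curve must be winter-peaked in every relative year
  cc <- cohort_config(n_children = 60, base_hazard = 0, spike_hazard = 0,
                      gap_rate = 0, seed = 13,
                      enrolment_window = as.Date(c("2009-01-01",
                                                   "2010-12-31")))
  sim <- cohort_cache("seasonal60", cc)
  incl <- shape_inclusion(sim$diaries)
  expect_gt(incl$n_shape_included, 10)
  tn <- build_tensor(sim$diaries, incl)
  cold <- apply(tn[, "cold", , drop = FALSE], 3, mean)
  for (y in 1:3) {
    jan <- cold[(y - 1) * 12 + 1]
    jul <- cold[(y - 1) * 12 + 7]
    expect_gt(jan, jul + 0.05)
  }
})
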