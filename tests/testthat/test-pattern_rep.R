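test_that("daily codes follow the symptom order and healthy days vanish", {
  expect_equal(encode_day(c(1, 1, 0)), "110")
  expect_equal(encode_day(c(0, 1, 0)), "010")
  expect_equal(encode_day(c(1, 0, 1)), "101")
  expect_true(is.na(encode_day(c(0, 0, 0))))
  expect_equal(encode_day(c(0, 0, 0), healthy_as_pattern = TRUE), "000")
  expect_error(encode_day(c(1, NA, 0)), "missing")
  expect_error(encode_day(c(1, 2, 0)), "0/1")
})

test_that("encode/decode is a bijection over all non-empty subsets", {
  symptoms <- default_symptoms()
  M <- length(symptoms)
  codes <- character(0)
  for (i in seq_len(2^M - 1)) {
    bits <- as.integer(intToBits(i)[1:M])
    code <- encode_day(bits)
    expect_identical(decode_pattern(code, symptoms), symptoms[bits == 1L])
    codes <- c(codes, code)
  }
  expect_equal(length(unique(codes)), 2^M - 1)
  expect_equal(pattern_label("1100000000", symptoms), "Cough + Cold")
})

test_that("frequency rows reproduce a hand-built diary-year", {
  # 10 cough-only, 19 wheeze-only, 5 cough+cold days in year one
  sym <- c("cough", "cold", "wheeze")
  v <- matrix(0L, 1096, 3)
  v[1:10, 1] <- 1L
  v[21:39, 3] <- 1L
  v[51:55, 1] <- 1L; v[51:55, 2] <- 1L
  d <- make_diary(v, start = "2020-01-01", child_id = "001", symptoms = sym)
  vocab <- build_vocabulary(list(d))
  Fm <- build_frequency_matrix(list(d), vocab)
  expect_equal(rownames(Fm), c("001-y1", "001-y2", "001-y3"))
  expect_equal(unname(Fm["001-y1", "100"]), 10)
  expect_equal(unname(Fm["001-y1", "001"]), 19)
  expect_equal(unname(Fm["001-y1", "110"]), 5)
  expect_equal(unname(rowSums(Fm)), c(34, 0, 0))  # healthy years: zero rows
  expect_equal(vocab$label[vocab$code == "110"], "Cough + Cold")
})

test_that("vocabulary and row sums agree with brute-force tallies", {
  sim <- cohort_cache("mixed120", cohort_config(n_children = 120, seed = 8))
  incl <- pattern_inclusion(sim$diaries)
  vocab <- build_vocabulary(sim$diaries, incl)
  Fm <- build_frequency_matrix(sim$diaries, vocab, incl)

  # independent one-pass set construction and per-year day tally
  brute_codes <- character(0)
  brute_rowsum <- integer(0)
  for (i in seq_along(sim$diaries)) {
    ny <- incl$children$pattern_years[i]
    if (ny == 0) next
    d <- sim$diaries[[i]]
    s <- assign_slots(d, quiet = TRUE)
    v <- diary_values(d)
    keep <- !is.na(s$rel_year) & s$rel_year <= ny &
      rowSums(is.na(v)) == 0 & rowSums(v, na.rm = TRUE) > 0
    codes <- apply(v[keep, , drop = FALSE], 1, paste, collapse = "")
    brute_codes <- union(brute_codes, codes)
    brute_rowsum <- c(brute_rowsum, vapply(seq_len(ny), function(y) {
      sum(s$rel_year[keep] == y)
    }, integer(1)))
  }
  expect_setequal(vocab$code, brute_codes)
  expect_identical(vocab$code, sort(vocab$code))
  expect_lte(nrow(vocab), 2^10)
  expect_equal(unname(rowSums(Fm)), brute_rowsum)
})

test_that("frequencies ignore day order and freeze against new patterns", {
  sym <- c("a", "b")
  v <- matrix(0L, 400, 2)
  v[5:30, 1] <- 1L
  d1 <- make_diary(v, child_id = "p1", symptoms = sym)
  # shuffle days within each month block: counts must not change
  s <- assign_slots(d1)
  v3 <- v
  for (t in unique(s$slot[!is.na(s$slot)])) {
    idx <- which(s$slot == t)
    set.seed(t)
    v3[idx, ] <- v[sample(idx), ]
  }
  d3 <- make_diary(v3, child_id = "p1", symptoms = sym)
  vocab <- build_vocabulary(list(d1))
  expect_equal(
    suppressWarnings(build_frequency_matrix(list(d1), vocab)),
    suppressWarnings(build_frequency_matrix(list(d3), vocab)),
    ignore_attr = TRUE)

  # a frozen vocabulary routes unseen patterns to 'other'
  v4 <- v; v4[50, 2] <- 1L
  d4 <- make_diary(v4, child_id = "p2", symptoms = sym)
  expect_warning(F4 <- build_frequency_matrix(list(d4), vocab), "other")
  expect_equal(unname(F4[1, "other"]), 1)
})
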