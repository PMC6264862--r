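#' Recorded-day counts per diary
#'
#' A day counts as recorded if its row carries at least one non-missing
#' symptom value; all-missing rows (gaps) do not count. Summaries include
#' the fraction of diaries that are fully recorded for the whole target
#' follow-up and the fraction reaching at least 1000 recorded days.
#'
#' @param cohort Non-empty list of [diary()] objects.
#' @param full_days Target follow-up length used for the "complete"
#'   fraction (default 1096).
#' @return List with `counts` (named integer vector per child) and
#'   `summary` (data frame: n, median, fraction >= 1000 days, fraction
#'   fully recorded).
#' @export
length_distribution <- function(cohort, full_days = 1096) {
  if (length(cohort) == 0) stop("length_distribution: empty cohort")
  counts <- vapply(cohort, function(d) {
    v <- diary_values(d)
    sum(rowSums(!is.na(v)) > 0L)
  }, integer(1))
  names(counts) <- vapply(cohort, attr, character(1), "child_id")
  list(counts = counts,
       summary = data.frame(
         n = length(counts),
         median_days = stats::median(counts),
         frac_ge_1000 = mean(counts >= 1000),
         frac_full = mean(counts >= full_days)))
}

#' Proportion of missing records by age
#'
#' For each age (days since enrolment) the fraction of children whose
#' record for that day is missing — either an all-missing row or a day
#' past their dropout — among children whose target window covers that
#' age. Dropout concentrated at well-defined ages shows up as upward
#' jumps in this curve.
#'
#' @param cohort Non-empty list of [diary()] objects.
#' @param max_age Oldest age (in days) evaluated; defaults to the longest
#'   diary in the cohort.
#' @return Data frame with columns `age` and `prop_missing`.
#' @export
missing_fraction_by_age <- function(cohort, max_age = NULL) {
  if (length(cohort) == 0) stop("missing_fraction_by_age: empty cohort")
  lens <- vapply(cohort, nrow, integer(1))
  if (is.null(max_age)) max_age <- max(lens)
  miss <- matrix(TRUE, nrow = length(cohort), ncol = max_age)
  for (i in seq_along(cohort)) {
    v <- diary_values(cohort[[i]])
    upto <- min(lens[i], max_age)
    miss[i, seq_len(upto)] <- rowSums(!is.na(v))[seq_len(upto)] == 0L
  }
  data.frame(age = seq_len(max_age), prop_missing = colMeans(miss))
}

#' Symptom burden versus diary length
#'
#' Burden is the mean over all observed day-symptom cells of a diary, so
#' it measures average symptom load up to dropout. Under dropout that is
#' unrelated to symptom load (missing at random in the sense relevant
#' here) the correlation between burden and diary length is near zero.
#'
#' @param cohort Non-empty list of [diary()] objects.
#' @return List with `table` (child_id, length, burden) and
#'   `correlation` (Pearson correlation of the two columns). Children
#'   with zero observed cells are excluded with a warning.
#' @export
burden_vs_length <- function(cohort) {
  if (length(cohort) == 0) stop("burden_vs_length: empty cohort")
  tab <- do.call(rbind, lapply(cohort, function(d) {
    v <- diary_values(d)
    n_obs <- sum(!is.na(v))
    data.frame(child_id = attr(d, "child_id"),
               length = sum(rowSums(!is.na(v)) > 0L),
               burden = if (n_obs > 0) mean(v, na.rm = TRUE) else NA_real_)
  }))
  drop <- is.na(tab$burden)
  if (any(drop)) {
    warning("burden_vs_length: excluding ", sum(drop),
            " child(ren) with zero observed days")
    tab <- tab[!drop, ]
  }
  r <- if (nrow(tab) > 2) stats::cor(tab$length, tab$burden) else NA_real_
  list(table = tab, correlation = r)
}

# Shared inclusion engine. A month-slot satisfies the tolerance iff the
# month was observed on at least (days in month - max_missing) fully
# recorded days; slots the diary never reaches fail automatically.
inclusion_engine <- function(cohort, max_missing = 15) {
  if (length(cohort) == 0) stop("inclusion: empty cohort")
  per_child <- lapply(cohort, function(d) {
    ss <- slot_summary(d)
    ok <- !is.na(ss$calendar_days) &
      ss$observed >= ss$calendar_days - max_missing
    missing_days <- ifelse(is.na(ss$calendar_days), NA_integer_,
                           ss$calendar_days - ss$observed)
    list(ok = ok, missing_days = missing_days)
  })
  ok_mat <- t(vapply(per_child, function(x) x$ok, logical(36)))
  shape_included <- rowSums(ok_mat) == 36L
  md_mat <- t(vapply(per_child,
                     function(x) as.numeric(x$missing_days), numeric(36)))
  complete <- shape_included &
    apply(md_mat, 1, function(md) all(!is.na(md) & md == 0))
  # participation year y = slots 12(y-1)+1 .. 12y; prefix-wise inclusion
  year_ok <- sapply(1:3, function(y) {
    rowSums(ok_mat[, (y - 1) * 12 + 1:12, drop = FALSE]) == 12L
  })
  year_ok <- matrix(year_ok, ncol = 3)
  n_years <- apply(year_ok, 1, function(yo) {
    bad <- which(!yo)
    if (length(bad) == 0) 3L else bad[1] - 1L
  })
  children <- data.frame(
    child_id = vapply(cohort, attr, character(1), "child_id"),
    complete = complete,
    shape_included = shape_included,
    pattern_years = n_years,
    year1 = n_years >= 1L, year2 = n_years >= 2L, year3 = n_years >= 3L,
    stringsAsFactors = FALSE)
  structure(list(
    children = children,
    n_complete = sum(complete),
    n_shape_included = sum(shape_included),
    n_pattern_rows = sum(n_years),
    max_missing = max_missing), class = "inclusion_result")
}

#' @export
print.inclusion_result <- function(x, ...) {
  cat("<inclusion> ", nrow(x$children), " diaries: ",
      x$n_complete, " complete, ", x$n_shape_included,
      " shape-included (<= ", x$max_missing, " missing days/month in all ",
      "36 months), ", x$n_pattern_rows, " pattern diary-years\n", sep = "")
  invisible(x)
}

#' Shape-representation inclusion rule
#'
#' A diary enters the shape representation iff every one of its 36
#' aligned month-slots was observed with at most `max_missing` missing
#' days (default 15). Diaries with zero missing days in all slots are
#' additionally flagged `complete`.
#'
#' @param cohort Non-empty list of [diary()] objects.
#' @param max_missing Per-month missing-day tolerance (default 15).
#' @return An `inclusion_result` with per-child flags and counts.
#' @export
shape_inclusion <- function(cohort, max_missing = 15) {
  inclusion_engine(cohort, max_missing)
}

#' Pattern-representation inclusion rule
#'
#' Each participation year of a diary (month-slots 1-12, 13-24, 25-36)
#' becomes one diary-year row iff all twelve of its slots satisfy the
#' per-month tolerance, and years are included prefix-wise: a later year
#' cannot enter if an earlier one failed. Shape-included diaries
#' therefore contribute exactly three rows; diaries with a clean first
#' two years but a heavily missing third contribute two.
#'
#' @inheritParams shape_inclusion
#' @return An `inclusion_result`; `children$pattern_years` gives the
#'   number of included years per child.
#' @export
pattern_inclusion <- function(cohort, max_missing = 15) {
  inclusion_engine(cohort, max_missing)
}
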