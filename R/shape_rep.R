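#' Assign diary days to aligned (relative year, calendar month) slots
#'
#' Calendar alignment with cut-and-reposition: diaries are centred on the
#' calendar year, the segment preceding a first of January is cut and
#' moved twelve months later, cascading, so that the i-th chronological
#' occurrence of calendar month `mu` in a diary lands in relative year
#' `i`, slot month `mu`. This preserves seasonality point-by-point across
#' children with different enrolment dates while discarding serial
#' ordering across years. A 36-month diary fills all `T = 36` slots with
#' no collisions; days falling in a fourth or later occurrence of a month
#' are dropped with a warning.
#'
#' @param d A [diary()].
#' @param max_years Number of relative years kept (default 3).
#' @param quiet Suppress the dropped-days warning (used by bulk callers
#'   for which trailing partial months are routine).
#' @return A data frame with one row per diary day: `date`, `cal_year`,
#'   `cal_month`, `rel_year` (NA for dropped days) and `slot`
#'   (`(rel_year - 1) * 12 + cal_month`, in 1..36).
#' @export
assign_slots <- function(d, max_years = 3, quiet = FALSE) {
  stopifnot(is_diary(d))
  lt <- as.POSIXlt(d$date)
  cal_year <- lt$year + 1900L
  cal_month <- lt$mon + 1L
  key <- cal_year * 12L + cal_month
  uk <- sort(unique(key))          # chronological distinct months
  um <- ((uk - 1L) %% 12L) + 1L    # calendar month of each
  occ <- stats::ave(seq_along(uk), um, FUN = seq_along)
  rel_year <- occ[match(key, uk)]
  dropped <- rel_year > max_years
  if (any(dropped)) {
    if (!quiet) {
      warning("assign_slots: ", sum(dropped),
              " day(s) beyond relative year ", max_years, " dropped")
    }
    rel_year[dropped] <- NA_integer_
  }
  data.frame(date = d$date, cal_year = cal_year, cal_month = cal_month,
             rel_year = rel_year,
             slot = (rel_year - 1L) * 12L + cal_month)
}

days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  n <- base[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  n + ifelse(month == 2L & leap, 1L, 0L)
}

# Per-slot bookkeeping for one diary: calendar length of the month each
# slot draws from, number of observed (fully recorded) days, and per-
# symptom presence counts. Slots never reached by the diary have
# calendar_days = NA and observed = 0.
slot_summary <- function(d, slots = NULL) {
  if (is.null(slots)) slots <- assign_slots(d, quiet = TRUE)
  M <- length(attr(d, "symptoms"))
  v <- diary_values(d)
  obs_day <- rowSums(is.na(v)) == 0L
  cal_days <- rep(NA_integer_, 36)
  observed <- integer(36)
  present <- matrix(0L, nrow = M, ncol = 36,
                    dimnames = list(attr(d, "symptoms"), NULL))
  keep <- !is.na(slots$rel_year)
  for (t in unique(slots$slot[keep])) {
    in_t <- keep & slots$slot == t
    cal_days[t] <- days_in_month(slots$cal_year[in_t][1],
                                 slots$cal_month[in_t][1])
    observed[t] <- sum(obs_day[in_t])
    if (observed[t] > 0) {
      present[, t] <- colSums(v[in_t & obs_day, , drop = FALSE])
    }
  }
  list(calendar_days = cal_days, observed = observed, present = present)
}

#' Monthly symptom proportions for one diary
#'
#' Cell (m, t) is the fraction of observed days in month-slot t on which
#' symptom m was present; the denominator is observed days, not calendar
#' days, so that tolerated missing days bias the estimate minimally. A
#' slot whose month was observed on fewer than (days in month - 15) days
#' violates the missingness tolerance and is returned as `NA`.
#'
#' @param d A [diary()].
#' @param slots Optional precomputed [assign_slots()] result.
#' @param max_missing Missing-day tolerance per month (default 15).
#' @return Numeric M x 36 matrix with symptom names as row names; `NA`
#'   for undefined slots.
#' @export
monthly_proportions <- function(d, slots = NULL, max_missing = 15) {
  ss <- slot_summary(d, slots)
  ok <- !is.na(ss$calendar_days) &
    ss$observed >= ss$calendar_days - max_missing & ss$observed > 0
  if (!all(ok)) {
    warning("monthly_proportions: ", sum(!ok),
            " slot(s) undefined (missingness tolerance violated)")
  }
  prop <- sweep(ss$present, 2, ss$observed, "/")
  prop[, !ok] <- NA_real_
  prop
}

#' Build the aligned children x symptoms x months tensor
#'
#' Stacks the [monthly_proportions()] matrices of all shape-included
#' children into an I x M x 36 array of monthly symptom proportions.
#'
#' @param cohort List of [diary()] objects.
#' @param inclusion Result of [shape_inclusion()] for `cohort`; computed
#'   if missing.
#' @param max_missing Missing-day tolerance per month (default 15).
#' @return An object of class `symptom_tensor`: a numeric array with
#'   `dimnames` (child ids, symptoms, slot labels `y<year>m<month>`).
#' @export
build_tensor <- function(cohort, inclusion = NULL, max_missing = 15) {
  if (is.null(inclusion)) inclusion <- shape_inclusion(cohort,
                                                      max_missing = max_missing)
  if (length(cohort) != nrow(inclusion$children)) {
    stop("build_tensor: inclusion does not match cohort")
  }
  keep <- which(inclusion$children$shape_included)
  if (length(keep) == 0) stop("build_tensor: no shape-included children")
  symptoms <- attr(cohort[[keep[1]]], "symptoms")
  M <- length(symptoms)
  slot_labels <- paste0("y", rep(1:3, each = 12), "m", rep(1:12, 3))
  X <- array(NA_real_, dim = c(length(keep), M, 36),
             dimnames = list(inclusion$children$child_id[keep],
                             symptoms, slot_labels))
  for (k in seq_along(keep)) {
    X[k, , ] <- monthly_proportions(cohort[[keep[k]]],
                                    max_missing = max_missing)
  }
  structure(X, class = c("symptom_tensor", "array"))
}

#' Matricize a symptom tensor over its feature modes
#'
#' Flattens the I x M x T tensor into an I x MT matrix in which each child
#' is one row; columns are ordered symptom-major, column index
#' `(m - 1) * T + t`, and carry composite names `<symptom>.y<year>m<month>`.
#'
#' @param tensor A `symptom_tensor` from [build_tensor()].
#' @return A numeric matrix with attribute `column_keys`, a data frame
#'   mapping each column to its (symptom, slot, year, month).
#' @export
matricize <- function(tensor) {
  if (anyNA(tensor)) stop("matricize: tensor has undefined cells")
  I <- dim(tensor)[1]; M <- dim(tensor)[2]; T <- dim(tensor)[3]
  X <- matrix(NA_real_, nrow = I, ncol = M * T)
  keys <- data.frame(column = seq_len(M * T),
                     symptom = rep(dimnames(tensor)[[2]], each = T),
                     m = rep(seq_len(M), each = T),
                     t = rep(seq_len(T), M))
  keys$year <- (keys$t - 1L) %/% 12L + 1L
  keys$month <- (keys$t - 1L) %% 12L + 1L
  for (m in seq_len(M)) {
    X[, (m - 1L) * T + seq_len(T)] <- tensor[, m, , drop = TRUE]
  }
  rownames(X) <- dimnames(tensor)[[1]]
  colnames(X) <- paste0(keys$symptom, ".", dimnames(tensor)[[3]][keys$t])
  attr(X, "column_keys") <- keys
  X
}

#' Invert [matricize()]
#'
#' @param X Matrix produced by [matricize()].
#' @param M,T Numbers of symptoms and month slots.
#' @param dimnames Optional dimnames for the rebuilt tensor.
#' @return A `symptom_tensor` with `unmatricize(matricize(A)) == A`.
#' @export
unmatricize <- function(X, M, T = 36, dimnames = NULL) {
  stopifnot(ncol(X) == M * T)
  A <- array(NA_real_, dim = c(nrow(X), M, T), dimnames = dimnames)
  for (m in seq_len(M)) {
    A[, m, ] <- X[, (m - 1L) * T + seq_len(T)]
  }
  structure(A, class = c("symptom_tensor", "array"))
}
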