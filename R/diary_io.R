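#' Construct a diary object
#'
#' A diary is one child's daily record of binary symptom indicators. It is
#' stored as a data frame with a `date` column (class `Date`, strictly
#' increasing, daily resolution) and one integer column per symptom taking
#' values 0, 1 or `NA`. A day on which nothing was recorded is kept as a row
#' whose symptom values are all `NA`, so diary length (participation) and
#' missingness remain separable.
#'
#' @param child_id Character scalar identifying the child.
#' @param dates `Date` vector of consecutive days.
#' @param values Matrix or data frame of symptom indicators
#'   (`length(dates)` rows), values in \{0, 1, NA\}.
#' @param symptoms Character vector of symptom names, in the order that
#'   defines pattern codes.
#' @return An object of class `diary`.
#' @export
diary <- function(child_id, dates, values, symptoms) {
  values <- as.matrix(values)
  if (nrow(values) != length(dates)) {
    stop("diary: ", length(dates), " dates but ", nrow(values), " value rows")
  }
  if (ncol(values) != length(symptoms)) {
    stop("diary: ", length(symptoms), " symptoms but ", ncol(values),
         " value columns")
  }
  storage.mode(values) <- "integer"
  d <- data.frame(date = as.Date(dates))
  for (j in seq_along(symptoms)) d[[symptoms[j]]] <- values[, j]
  structure(d,
            child_id = as.character(child_id),
            symptoms = symptoms,
            class = c("diary", "data.frame"))
}

#' @export
print.diary <- function(x, ...) {
  cat("<diary> child", attr(x, "child_id"), "-", nrow(x), "days,",
      length(attr(x, "symptoms")), "symptoms,",
      sum(!stats::complete.cases(diary_values(x))), "days with missings\n")
  invisible(x)
}

#' Symptom values of a diary as an integer matrix
#'
#' @param d A `diary`.
#' @return Integer matrix, days x symptoms, values 0/1/NA.
#' @export
diary_values <- function(d) {
  m <- as.matrix(as.data.frame(d)[, attr(d, "symptoms"), drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' @rdname diary
#' @param x Object to test.
#' @export
is_diary <- function(x) inherits(x, "diary")

validate_diary <- function(d, where = "diary") {
  dates <- d$date
  if (anyDuplicated(dates)) {
    stop(where, ": duplicate date ", dates[anyDuplicated(dates)])
  }
  if (is.unsorted(dates)) stop(where, ": dates not increasing")
  v <- diary_values(d)
  bad <- which(!(is.na(v) | v == 0L | v == 1L), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(where, ": non-binary value ", v[bad[1, 1], bad[1, 2]],
         " in column '", attr(d, "symptoms")[bad[1, 2]],
         "' on ", dates[bad[1, 1]])
  }
  invisible(d)
}

#' Read a diary CSV file
#'
#' The on-disk dialect is comma-separated with ISO-8601 dates, a `date`
#' column and one column per symptom; missing cells are written as `NA`.
#' Gaps between consecutive dates are materialised as all-missing rows so
#' that every diary covers a contiguous daily grid.
#'
#' @param path Path to the CSV file.
#' @param symptoms Character vector of expected symptom columns, in order.
#' @param child_id Child identifier; defaults to the file name without
#'   extension.
#' @return A validated `diary`.
#' @export
read_diary <- function(path, symptoms, child_id = NULL) {
  if (!file.exists(path)) stop("read_diary: no such file: ", path)
  if (is.null(child_id)) {
    child_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!"date" %in% names(raw)) stop("read_diary: missing 'date' column in ", path)
  missing_cols <- setdiff(symptoms, names(raw))
  if (length(missing_cols) > 0) {
    stop("read_diary: missing symptom column(s) ",
         paste(missing_cols, collapse = ", "), " in ", path)
  }
  dates <- as.Date(raw$date)
  if (anyNA(dates)) {
    stop("read_diary: unparseable date in row ", which(is.na(dates))[1])
  }
  ord <- order(dates)
  dates <- dates[ord]
  if (anyDuplicated(dates)) {
    stop("read_diary: duplicate date ", dates[anyDuplicated(dates)],
         " in ", path)
  }
  v <- matrix(NA_integer_, nrow = length(dates), ncol = length(symptoms))
  for (j in seq_along(symptoms)) {
    col <- raw[[symptoms[j]]][ord]
    out <- rep(NA_integer_, length(col))
    ok <- !is.na(col) & col != "NA" & col != ""
    parsed <- suppressWarnings(as.integer(col[ok]))
    if (anyNA(parsed) || any(!parsed %in% c(0L, 1L))) {
      bad <- which(ok)[which(is.na(parsed) | !parsed %in% c(0L, 1L))[1]]
      stop("read_diary: non-binary value '", col[bad], "' in column '",
           symptoms[j], "' row ", bad, " of ", path)
    }
    out[ok] <- parsed
    v[, j] <- out
  }
  # materialise calendar gaps as all-missing rows
  full <- seq(min(dates), max(dates), by = "day")
  if (length(full) > length(dates)) {
    idx <- match(full, dates)
    v <- v[idx, , drop = FALSE]
    dates <- full
  }
  validate_diary(diary(child_id, dates, v, symptoms), where = "read_diary")
}

#' Write a diary to CSV
#'
#' Inverse of [read_diary()]: `read_diary(write_diary(d, p), symptoms)`
#' returns a diary identical to `d` up to gap materialisation (which
#' `diary` objects already carry).
#'
#' @param d A `diary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_diary <- function(d, path) {
  stopifnot(is_diary(d))
  out <- data.frame(date = format(d$date, "%Y-%m-%d"))
  for (s in attr(d, "symptoms")) out[[s]] <- d[[s]]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a cohort of diaries to a directory
#'
#' One CSV per child (named `<child_id>.csv`) plus a `manifest.csv` with
#' columns `child_id` and `enrolment`.
#'
#' @param cohort List of `diary` objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(cohort, function(d) attr(d, "child_id"), character(1))
  enrol <- as.Date(vapply(cohort, function(d) as.character(min(d$date)),
                          character(1)))
  for (d in cohort) {
    write_diary(d, file.path(dir, paste0(attr(d, "child_id"), ".csv")))
  }
  utils::write.csv(
    data.frame(child_id = ids, enrolment = format(enrol, "%Y-%m-%d")),
    file.path(dir, "manifest.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing per-child CSVs and `manifest.csv`.
#' @param symptoms Character vector of symptom columns, in order.
#' @return List of `diary` objects, in manifest order.
#' @export
read_cohort <- function(dir, symptoms) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"),
                        stringsAsFactors = FALSE,
                        colClasses = "character")
  lapply(mf$child_id, function(id) {
    read_diary(file.path(dir, paste0(id, ".csv")), symptoms, child_id = id)
  })
}
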