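#' Encode one day's symptom combination as a pattern code
#'
#' The combination of symptoms present on a day is encoded as a binary
#' string over the configured symptom order: position m is "1" iff
#' symptom m is present. With order (cough, cold, wheeze), a day with
#' cough and cold but no wheeze encodes as "110", cold only as "010",
#' cough and wheeze as "101". An all-zero (healthy) day returns
#' `NA_character_` and contributes no pattern: the bag-of-patterns view
#' treats healthy days as empty, exactly as a text model ignores blank
#' documents' non-words.
#'
#' @param values Numeric/integer vector of 0/1 indicators, one per
#'   symptom, in symptom order. Missing values are a contract violation:
#'   days with any missing value must be skipped upstream.
#' @param healthy_as_pattern If `TRUE`, an all-zero day yields the
#'   all-zero code instead of the sentinel (sensitivity analyses only).
#' @return A pattern code string, or `NA_character_` for a healthy day.
#' @export
encode_day <- function(values, healthy_as_pattern = FALSE) {
  if (anyNA(values)) {
    stop("encode_day: missing symptom value; skip incomplete days upstream")
  }
  if (!all(values %in% c(0, 1))) {
    stop("encode_day: values must be 0/1")
  }
  if (!healthy_as_pattern && sum(values) == 0) return(NA_character_)
  paste(as.integer(values), collapse = "")
}

#' Decode a pattern code into a symptom subset
#'
#' Inverse of [encode_day()]: `decode_pattern(encode_day(x), symptoms)`
#' returns the names of the symptoms present in `x`.
#'
#' @param code Pattern code string.
#' @param symptoms Ordered symptom names (same order used to encode).
#' @return Character vector of present symptoms.
#' @export
decode_pattern <- function(code, symptoms) {
  bits <- as.integer(strsplit(code, "")[[1]])
  if (length(bits) != length(symptoms)) {
    stop("decode_pattern: code length ", length(bits), " but ",
         length(symptoms), " symptoms")
  }
  symptoms[bits == 1L]
}

#' Human-readable label for a pattern code
#'
#' @inheritParams decode_pattern
#' @return The present symptom names joined with " + " and capitalised,
#'   e.g. "Cough + Cold".
#' @export
pattern_label <- function(code, symptoms) {
  present <- decode_pattern(code, symptoms)
  present <- paste0(toupper(substring(present, 1, 1)), substring(present, 2))
  paste(present, collapse = " + ")
}

# All pattern codes of the included diary-years of one diary, one code
# per symptomatic fully observed day (healthy and incomplete days are
# skipped). Returns a list with one character vector per included year.
diary_year_codes <- function(d, n_years, healthy_as_pattern = FALSE) {
  slots <- assign_slots(d, quiet = TRUE)
  v <- diary_values(d)
  obs <- rowSums(is.na(v)) == 0L
  out <- vector("list", n_years)
  for (y in seq_len(n_years)) {
    in_year <- !is.na(slots$rel_year) & slots$rel_year == y & obs
    rows <- which(in_year)
    codes <- vapply(rows, function(r) {
      code <- encode_day(v[r, ], healthy_as_pattern = healthy_as_pattern)
      if (is.na(code)) "" else code
    }, character(1))
    out[[y]] <- codes[codes != ""]
  }
  out
}

#' Build the observed pattern vocabulary
#'
#' The vocabulary is the lexicographically sorted set of distinct daily
#' pattern codes observed across all included diary-years. Ten symptoms
#' admit up to 2^10 codes in theory; rare symptoms keep the observed
#' count far smaller.
#'
#' @param cohort List of [diary()] objects.
#' @param inclusion Result of [pattern_inclusion()]; computed if missing.
#' @param healthy_as_pattern Include the all-zero code for healthy days
#'   (default `FALSE`).
#' @return An object of class `pattern_vocabulary`: data frame with
#'   columns `code` and `label`.
#' @export
build_vocabulary <- function(cohort, inclusion = NULL,
                             healthy_as_pattern = FALSE) {
  if (is.null(inclusion)) inclusion <- pattern_inclusion(cohort)
  symptoms <- attr(cohort[[1]], "symptoms")
  codes <- character(0)
  for (i in seq_along(cohort)) {
    ny <- inclusion$children$pattern_years[i]
    if (ny == 0) next
    codes <- union(codes,
                   unique(unlist(diary_year_codes(cohort[[i]], ny,
                                                  healthy_as_pattern))))
  }
  if (length(codes) == 0) stop("build_vocabulary: no patterns observed")
  codes <- sort(codes)
  structure(data.frame(
    code = codes,
    label = vapply(codes, pattern_label, character(1), symptoms = symptoms),
    row.names = NULL, stringsAsFactors = FALSE),
    class = c("pattern_vocabulary", "data.frame"))
}

#' Build the diary-year by pattern frequency matrix
#'
#' Row j counts, for one included diary-year, the number of observed
#' days carrying each vocabulary pattern; rows are keyed
#' `<child_id>-y<year>`. Row sums equal the number of fully observed
#' symptomatic days in that year. Patterns observed in the data but
#' absent from a frozen vocabulary are routed to a reserved `other`
#' column with a warning.
#'
#' @param cohort List of [diary()] objects.
#' @param vocabulary A `pattern_vocabulary` (built from `cohort` if
#'   missing).
#' @param inclusion Result of [pattern_inclusion()]; computed if missing.
#' @param healthy_as_pattern Count all-zero days as a pattern (default
#'   `FALSE`).
#' @return Integer matrix J x G with row names `<child>-y<k>` and column
#'   names the vocabulary codes (plus `other` if needed), with attribute
#'   `row_info` (data frame: child_id, year).
#' @export
build_frequency_matrix <- function(cohort, vocabulary = NULL,
                                   inclusion = NULL,
                                   healthy_as_pattern = FALSE) {
  if (is.null(inclusion)) inclusion <- pattern_inclusion(cohort)
  if (is.null(vocabulary)) {
    vocabulary <- build_vocabulary(cohort, inclusion, healthy_as_pattern)
  }
  G <- nrow(vocabulary)
  rows <- list(); keys <- list()
  other <- FALSE
  for (i in seq_along(cohort)) {
    ny <- inclusion$children$pattern_years[i]
    if (ny == 0) next
    ycodes <- diary_year_codes(cohort[[i]], ny, healthy_as_pattern)
    for (y in seq_len(ny)) {
      counts <- integer(G + 1L)
      tab <- table(ycodes[[y]])
      idx <- match(names(tab), vocabulary$code)
      unknown <- is.na(idx)
      if (any(unknown)) {
        other <- TRUE
        counts[G + 1L] <- sum(tab[unknown])
        warning("build_frequency_matrix: ", sum(unknown),
                " pattern(s) outside vocabulary routed to 'other'")
      }
      counts[idx[!unknown]] <- as.integer(tab[!unknown])
      rows[[length(rows) + 1L]] <- counts
      keys[[length(keys) + 1L]] <-
        data.frame(child_id = inclusion$children$child_id[i], year = y,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("build_frequency_matrix: no included diary-years")
  F_mat <- do.call(rbind, rows)
  row_info <- do.call(rbind, keys)
  colnames(F_mat) <- c(vocabulary$code, "other")
  if (!other) F_mat <- F_mat[, seq_len(G), drop = FALSE]
  rownames(F_mat) <- paste0(row_info$child_id, "-y", row_info$year)
  attr(F_mat, "row_info") <- row_info
  F_mat
}
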