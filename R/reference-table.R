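# LMS reference tables: construction, validation, interpolation, I/O.

#' Build an LMS reference table
#'
#' An LMS reference table tabulates the Box-Cox power `L`, median `M` and
#' coefficient of variation `S` of a reference distribution by sex and age,
#' one row per (measure, sex, age). Several measures (e.g. height-for-age and
#' bmi-for-age) may live in one table; measurements are referenced by
#' interpolating L, M and S linearly in age within a measure and sex.
#'
#' @param data Data frame with columns `measure`, `sex`, `age`, `L`, `M`, `S`.
#'   `sex` must be `"male"`/`"female"`; ages must be strictly increasing
#'   within (measure, sex) with at least two rows each; `M > 0`, `S > 0`.
#' @param units Optional named character vector mapping measure to unit label.
#' @return A tibble of class `lms_reference`, sorted by (measure, sex, age).
#' @seealso [interpolate_lms()], [read_lms_reference()], [default_reference()]
#' @export
lms_reference <- function(data, units = NULL) {
  needed <- c("measure", "sex", "age", "L", "M", "S")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("reference table lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  tab <- tibble::as_tibble(data)[needed]
  if (!all(tab$sex %in% c("male", "female"))) {
    stop("`sex` must be 'male' or 'female'", call. = FALSE)
  }
  if (any(!is.finite(tab$age)) || any(tab$age < 0)) {
    stop("ages must be finite and >= 0", call. = FALSE)
  }
  check_lms(tab$L, tab$M, tab$S)
  tab <- dplyr::arrange(tab, .data$measure, .data$sex, .data$age)
  bad <- tab |>
    dplyr::summarise(
      n = dplyr::n(),
      dup = anyDuplicated(.data$age) > 0,
      .by = c("measure", "sex")
    )
  if (any(bad$n < 2)) {
    stop("each (measure, sex) needs at least 2 tabulated ages", call. = FALSE)
  }
  if (any(bad$dup)) {
    stop("duplicate (measure, sex, age) rows in reference table", call. = FALSE)
  }
  attr(tab, "units") <- units
  class(tab) <- c("lms_reference", class(tab))
  tab
}

#' Interpolate L, M, S at an age
#'
#' Returns the tabulated values exactly at a node and linear interpolation in
#' each of L, M and S between bracketing tabulated ages otherwise.
#'
#' @param table An [lms_reference()] table.
#' @param sex `"male"` or `"female"` (recycled against `age`).
#' @param age Age in decimal years; must lie within the tabulated range for
#'   the requested measure and sex.
#' @param measure Measure name; may be omitted when the table holds a single
#'   measure.
#' @return A tibble with columns `L`, `M`, `S` (one row per requested age).
#' @export
interpolate_lms <- function(table, sex, age, measure = NULL) {
  measure <- resolve_measure(table, measure)
  n <- max(length(sex), length(age))
  sex <- rep_len(sex, n)
  age <- rep_len(age, n)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("L", "M", "S")))
  for (sx in unique(sex)) {
    sub <- table[table$measure == measure & table$sex == sx, ]
    if (!nrow(sub)) {
      stop("no reference rows for measure '", measure, "', sex '", sx, "'",
        call. = FALSE
      )
    }
    idx <- which(sex == sx)
    a <- age[idx]
    lo <- min(sub$age)
    hi <- max(sub$age)
    if (any(!is.finite(a) | a < lo | a > hi)) {
      off <- a[which(!is.finite(a) | a < lo | a > hi)][1]
      stop(sprintf(
        "age %.3g outside reference range [%.3g, %.3g] for measure '%s', sex '%s'",
        off, lo, hi, measure, sx
      ), call. = FALSE)
    }
    for (comp in c("L", "M", "S")) {
      out[idx, comp] <- stats::approx(sub$age, sub[[comp]], xout = a)$y
    }
  }
  tibble::as_tibble(out)
}

resolve_measure <- function(table, measure) {
  if (is.null(measure)) {
    ms <- unique(table$measure)
    if (length(ms) != 1) {
      stop("table holds several measures; supply `measure`", call. = FALSE)
    }
    return(ms)
  }
  if (!measure %in% table$measure) {
    stop("measure '", measure, "' not present in reference table", call. = FALSE)
  }
  measure
}

# age limits per sex for one measure
reference_range <- function(table, measure = NULL) {
  measure <- resolve_measure(table, measure)
  table[table$measure == measure, ] |>
    dplyr::summarise(
      age_min = min(.data$age), age_max = max(.data$age),
      .by = "sex"
    )
}

# LMS at the oldest tabulated age (the adult endpoint) for a sex
adult_lms <- function(table, sex, measure = NULL) {
  measure <- resolve_measure(table, measure)
  rng <- reference_range(table, measure)
  amax <- rng$age_max[match(sex, rng$sex)]
  interpolate_lms(table, sex, amax, measure)
}

#' Reference a measurement vector
#'
#' Convenience wrapper: interpolates L, M, S and applies [sds()].
#'
#' @inheritParams interpolate_lms
#' @param x Measurements (recycled with `sex`/`age`).
#' @return Numeric vector of SDS values.
#' @export
reference_sds <- function(table, sex, age, x, measure = NULL) {
  lms <- interpolate_lms(table, sex, age, measure)
  sds(x, lms$L, lms$M, lms$S)
}

#' Read / write LMS reference CSV
#'
#' The on-disk dialect is a UTF-8, dot-decimal CSV with header
#' `measure,sex,age,L,M,S`; one file may hold several measures.
#'
#' @param path File path.
#' @return `read_lms_reference()` returns an [lms_reference()] table.
#' @export
read_lms_reference <- function(path) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(
      measure = readr::col_character(),
      sex = readr::col_character(),
      age = readr::col_double(),
      L = readr::col_double(),
      M = readr::col_double(),
      S = readr::col_double()
    )
  )
  lms_reference(raw)
}

#' @rdname read_lms_reference
#' @param table An [lms_reference()] table.
#' @export
write_lms_reference <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}
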