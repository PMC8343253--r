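# Analyte-level computations and per-age-group endocrine contrasts.

#' HOMA-IR insulin resistance index
#'
#' `HOMA-IR = insulin[mU/l] * glucose[mmol/l] / 22.5`. Insulin supplied in
#' pmol/L is first converted to mU/l by dividing by 6.945 (the conversion is
#' explicit in the `insulin_units` argument, never guessed from magnitudes).
#'
#' @param insulin Fasting insulin, `>= 0`.
#' @param glucose Fasting glucose in mmol/L, `> 0`.
#' @param insulin_units `"mU/l"` or `"pmol/L"`.
#' @return The index; bilinear in its arguments.
#' @examples
#' homa_ir(10, 4.5) # 2
#' homa_ir(69.45, 4.5, insulin_units = "pmol/L") # 2
#' @export
homa_ir <- function(insulin, glucose, insulin_units = c("mU/l", "pmol/L")) {
  insulin_units <- match.arg(insulin_units)
  if (any(!is.na(glucose) & glucose <= 0)) {
    stop("glucose must be positive", call. = FALSE)
  }
  if (any(!is.na(insulin) & insulin < 0)) {
    stop("insulin must be non-negative", call. = FALSE)
  }
  if (insulin_units == "pmol/L") insulin <- insulin / 6.945
  insulin * glucose / 22.5
}

# analytes whose analyses exclude children on a specific medication
analyte_medication_rules <- list(
  metformin = c("insulin", "HOMA-IR"),
  thyroxin = c("TSH", "FT4")
)

#' Per-age-group contrast of an analyte between weight groups
#'
#' Joins analyte values to the cohort's weight classification, applies the
#' analyte-specific medication exclusions (children flagged `metformin` are
#' removed from insulin and HOMA-IR analyses; `thyroxin` from TSH and FT4),
#' keeps one value per child per age group, and compares the strata per sex
#' and age group with Welch t-tests plus Holm-Sidak correction (family: the
#' age groups of one sex). `analyte = "HOMA-IR"` is derived on the fly from
#' same-visit insulin (pmol/L) and glucose rows when not itself present.
#' Contrasts are computed on raw concentrations (means of raw levels, as
#' they are conventionally plotted); set `log_scale = TRUE` to contrast log
#' concentrations for skewed analytes.
#'
#' @param cohort An SDS-annotated [growth_cohort()] with an `analytes` table.
#' @param analyte Analyte name as it appears in the `analytes` table.
#' @param group_a,group_b Weight categories to contrast (obese vs normal by
#'   default); the percent-difference profile is relative to `group_b`.
#' @param min_n,var_equal,alpha Passed to [compare_groups()].
#' @param log_scale Contrast `log(value)` instead of the raw concentration
#'   (percent differences are still reported on the raw-mean scale).
#' @return A `growth_comparison` tibble with a `sex` column; the `pct_diff`
#'   column is the percent-difference-by-age profile (use
#'   [max_group_difference()] on a sex's rows for its extremum in a window).
#' @export
analyte_contrast <- function(cohort, analyte,
                             group_a = "obese", group_b = "normal",
                             min_n = 6, var_equal = FALSE, alpha = 0.05,
                             log_scale = FALSE) {
  stopifnot(inherits(cohort, "growth_cohort"))
  if (!"weight_category" %in% names(cohort$observations)) {
    stop("observations lack weight_category; run reference_cohort() first",
      call. = FALSE
    )
  }
  d <- prep_analyte(cohort, analyte)
  if (log_scale) d$log_value <- log(d$value)

  out <- lapply(c("male", "female"), function(sx) {
    ds <- d[d$sex == sx, ]
    if (!nrow(ds)) {
      return(NULL)
    }
    res <- compare_groups(
      ds,
      value = if (log_scale) "log_value" else "value",
      group = "weight_category",
      group_a = group_a, group_b = group_b,
      min_n = min_n, var_equal = var_equal, alpha = alpha
    )
    if (log_scale) { # percent differences reported on the raw-mean scale
      raw <- ds |>
        dplyr::summarise(
          m = mean(.data$value),
          .by = c("age_group", "weight_category")
        ) |>
        tidyr::pivot_wider(
          names_from = "weight_category", values_from = "m"
        )
      res$pct_diff <- 100 * (raw[[group_a]][match(res$age_group, raw$age_group)] /
        raw[[group_b]][match(res$age_group, raw$age_group)] - 1)
    }
    dplyr::bind_cols(tibble::tibble(sex = sx), res)
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("growth_comparison", class(res))
  attr(res, "analyte") <- analyte
  res
}

#' Maximum percent reduction of an analyte in a pubertal age window
#'
#' Computes the obese-vs-normal percent difference of an analyte's mean over
#' the age groups of a (sex-specific) pubertal window and returns the
#' largest reduction. With `pool_sexes = TRUE`, the cells of the two sexes'
#' windows are aligned by their offset from the window start and pooled,
#' which is the natural estimator when the planted or expected effect is the
#' same relative change in both sexes (e.g. IGF-1); with `FALSE` only the
#' sexes named in `windows` are analysed separately and the deepest
#' reduction over all (sex, group) cells is returned.
#'
#' @param cohort An SDS-annotated [growth_cohort()] with analytes.
#' @param analyte Analyte name.
#' @param windows Named list of inclusive age-group windows per sex, e.g.
#'   `list(male = c(13, 14), female = c(12, 13))`.
#' @param group_a,group_b Weight categories contrasted.
#' @param pool_sexes Pool aligned window cells across sexes.
#' @return One-row tibble: `offset` (or `age_group`), `reduction_pct`
#'   (positive = lower in `group_a`).
#' @export
analyte_window_reduction <- function(cohort, analyte, windows,
                                     group_a = "obese", group_b = "normal",
                                     pool_sexes = TRUE) {
  d <- prep_analyte(cohort, analyte)
  keep <- rep(FALSE, nrow(d))
  offset <- rep(NA_integer_, nrow(d))
  for (sx in names(windows)) {
    w <- windows[[sx]]
    sel <- d$sex == sx & d$age_group >= w[1] & d$age_group <= w[2]
    keep <- keep | sel
    offset[sel] <- d$age_group[sel] - w[1]
  }
  d <- d[keep, ]
  d$offset <- offset[keep]
  if (!nrow(d)) stop("no analyte values in the requested window", call. = FALSE)
  if (pool_sexes) {
    res <- compare_groups(d, "value", "weight_category", group_a, group_b,
      by = "offset"
    )
    worst <- max_group_difference(
      dplyr::rename(res, age_group = "offset"), "percent",
      direction = "min"
    )
    tibble::tibble(offset = worst$age_group, reduction_pct = -worst$value)
  } else {
    rows <- lapply(names(windows), function(sx) {
      ds <- d[d$sex == sx, ]
      if (!nrow(ds)) {
        return(NULL)
      }
      res <- compare_groups(ds, "value", "weight_category", group_a, group_b)
      worst <- max_group_difference(res, "percent", direction = "min")
      tibble::tibble(
        sex = sx, age_group = worst$age_group,
        reduction_pct = -worst$value
      )
    })
    out <- dplyr::bind_rows(rows)
    out[which.max(out$reduction_pct), ]
  }
}

# shared preparation: analyte rows joined to weight category, sex, age group,
# medication exclusions applied, first value per child per age group
prep_analyte <- function(cohort, analyte) {
  obs <- cohort$observations
  an <- cohort$analytes
  if (is.null(an)) stop("cohort has no analytes table", call. = FALSE)
  if (analyte == "HOMA-IR" && !"HOMA-IR" %in% an$analyte) {
    an <- dplyr::bind_rows(an, derive_homa_ir(an))
  }
  d <- an[an$analyte == analyte, ]
  if (!nrow(d)) stop("analyte '", analyte, "' absent from cohort", call. = FALSE)
  for (med in names(analyte_medication_rules)) {
    if (analyte %in% analyte_medication_rules[[med]]) {
      flagged <- cohort$children$id[has_flag(cohort$children$flags, med)]
      d <- d[!d$child_id %in% flagged, ]
    }
  }
  key_obs <- paste(obs$child_id, round(obs$age, 3))
  i <- match(paste(d$child_id, round(d$age, 3)), key_obs)
  if (anyNA(i)) {
    for (k in which(is.na(i))) {
      cand <- which(obs$child_id == d$child_id[k])
      if (length(cand)) i[k] <- cand[which.min(abs(obs$age[cand] - d$age[k]))]
    }
  }
  d$weight_category <- obs$weight_category[i]
  d$sex <- cohort$children$sex[match(d$child_id, cohort$children$id)]
  d <- d[!is.na(d$weight_category), ]
  d$age_group <- assign_age_group(d$age)
  dedup_first_per_group(d)
}

# same-visit insulin (pmol/L) x glucose (mmol/L) -> HOMA-IR rows
derive_homa_ir <- function(analytes) {
  ins <- analytes[analytes$analyte == "insulin", ]
  glu <- analytes[analytes$analyte == "glucose", ]
  if (!nrow(ins) || !nrow(glu)) {
    stop("HOMA-IR needs both insulin and glucose rows", call. = FALSE)
  }
  i <- match(
    paste(ins$child_id, round(ins$age, 3)),
    paste(glu$child_id, round(glu$age, 3))
  )
  ok <- !is.na(i)
  ins_units <- unique(ins$units)
  tibble::tibble(
    child_id = ins$child_id[ok],
    age = ins$age[ok],
    analyte = "HOMA-IR",
    value = homa_ir(
      ins$value[ok], glu$value[i[ok]],
      insulin_units = if (identical(ins_units, "mU/l")) "mU/l" else "pmol/L"
    ),
    units = "index"
  )
}
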