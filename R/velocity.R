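# Growth-velocity computation with the longitudinal plausibility filters.

#' Compute growth velocities from consecutive visits
#'
#' For every pair of consecutive height observations of a child the growth
#' velocity is `(h2 - h1) / (t2 - t1)` in cm/year, assigned to the mean age
#' of the interval. A pair becomes a velocity record only if the interval is
#' between 3 months and 2 years and the mean age is at least 1.5 years;
#' records are then excluded as implausible when the velocity is negative,
#' below 1 cm/year at mean age under 14 (children grow at least 1 cm/year
#' until then), or more than 10 reference SD above the velocity median.
#' The record's weight category is taken from the first (earlier) observation
#' of the pair, or from the child's first-ever observation with
#' `assignment = "child_first"`.
#'
#' @param observations SDS-annotated observations (from [reference_cohort()])
#'   sorted by age within child; unsorted input is an error, not silently
#'   reordered.
#' @param velocity_reference An [lms_reference()] with a `velocity-for-age`
#'   measure, used for velocity SDS; when `NULL`, `gv_sds` is `NA`, the SDS
#'   filter is skipped and a warning is emitted.
#' @param assignment Which observation provides the record's weight category.
#' @param min_interval,max_interval,min_mean_age,max_sds Filter parameters
#'   (years, years, years, SDS).
#' @param dedup Keep only the first velocity per child per age group (the
#'   cross-sectional convention used for visualisation and statistics).
#' @return A list: `velocities` (tibble with `child_id`, `mean_age`,
#'   `interval`, `gv`, `gv_sds`, `age_group`, `weight_category`, `sex`) and
#'   `log` (per-rule exclusion counts).
#' @export
compute_velocities <- function(observations,
                               velocity_reference = NULL,
                               assignment = c("pair_first", "child_first"),
                               min_interval = 0.25, max_interval = 2.0,
                               min_mean_age = 1.5, max_sds = 10,
                               dedup = TRUE) {
  assignment <- match.arg(assignment)
  obs <- observations
  if (is.unsorted(order(obs$child_id)) &&
    anyDuplicated(rle(obs$child_id)$values)) {
    stop("observations must be grouped by child", call. = FALSE)
  }
  same <- obs$child_id[-1] == obs$child_id[-nrow(obs)]
  if (any(same & diff(obs$age) < 0)) {
    stop("observations must be time-sorted within child", call. = FALSE)
  }
  i1 <- which(same)
  i2 <- i1 + 1L
  interval <- obs$age[i2] - obs$age[i1]
  mean_age <- (obs$age[i1] + obs$age[i2]) / 2
  gv <- (obs$height[i2] - obs$height[i1]) / interval

  cat_idx <- if (assignment == "pair_first") {
    i1
  } else {
    match(obs$child_id[i1], obs$child_id) # first row of the child
  }

  rec <- tibble::tibble(
    child_id = obs$child_id[i1],
    sex = obs$sex[i1],
    mean_age = mean_age,
    interval = interval,
    gv = gv,
    weight_category = obs$weight_category[cat_idx]
  )

  rec$gv_sds <- NA_real_
  if (!is.null(velocity_reference)) {
    rng <- reference_range(velocity_reference, "velocity-for-age")
    lo <- rng$age_min[match(rec$sex, rng$sex)]
    hi <- rng$age_max[match(rec$sex, rng$sex)]
    lms <- interpolate_lms(
      velocity_reference, rec$sex, pmin(pmax(rec$mean_age, lo), hi),
      "velocity-for-age"
    )
    # lms_z rather than sds(): a zero velocity is a legal (filtered) input
    rec$gv_sds <- lms_z(pmax(rec$gv, 0), lms$L, lms$M, lms$S)
  } else {
    warning("no velocity reference supplied: gv_sds omitted and the ",
      "SDS plausibility filter skipped",
      call. = FALSE
    )
  }

  rules <- list(
    interval_short = interval < min_interval,
    interval_long = interval > max_interval,
    mean_age_young = mean_age < min_mean_age,
    negative_gv = gv < 0,
    slow_gv_under_14 = gv >= 0 & gv < 1 & mean_age < 14,
    gv_sds_implausible = !is.na(rec$gv_sds) & rec$gv_sds > max_sds
  )
  rules <- lapply(rules, function(r) !is.na(r) & r)
  drop <- Reduce(`|`, rules)
  log <- tibble::tibble(
    rule = names(rules),
    n_excluded = unname(vapply(rules, sum, integer(1)))
  )
  attr(log, "n_retained") <- sum(!drop)

  rec <- rec[!drop, ]
  rec$age_group <- assign_age_group(rec$mean_age)
  if (dedup) {
    rec <- dedup_first_per_group(rec, age_col = "mean_age")
  }
  list(velocities = rec, log = log)
}
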