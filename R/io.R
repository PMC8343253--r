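# Cohort CSV I/O and the aggregated analysis report.

#' Read / write cohort CSV tables
#'
#' Cohort files use dot-decimal, UTF-8 CSV with headers. `children.csv`
#' carries `id,sex,gestational_age_weeks,birth_length_cm,birth_weight_g,
#' mother_height_cm,father_height_cm,flags` (flags: `;`-separated tokens such
#' as `disease`, `medication`, `metformin`, `thyroxin`); `observations.csv`
#' carries `child_id,age,height,weight`; the optional `analytes.csv` is long
#' format `child_id,age,analyte,value,units`. Type violations (including
#' comma decimals) are rejected with row-numbered errors rather than
#' silently coerced.
#'
#' @param children_csv,observations_csv,analytes_csv File paths.
#' @return A [growth_cohort()].
#' @export
read_cohort <- function(children_csv, observations_csv, analytes_csv = NULL) {
  children <- strict_csv(children_csv, readr::cols(
    id = readr::col_character(),
    sex = readr::col_character(),
    stratum = readr::col_character(),
    gestational_age_weeks = readr::col_double(),
    birth_length_cm = readr::col_double(),
    birth_weight_g = readr::col_double(),
    mother_height_cm = readr::col_double(),
    father_height_cm = readr::col_double(),
    flags = readr::col_character(),
    .default = readr::col_double()
  ))
  children$flags[is.na(children$flags)] <- ""
  observations <- strict_csv(observations_csv, readr::cols(
    child_id = readr::col_character(),
    age = readr::col_double(),
    height = readr::col_double(),
    weight = readr::col_double(),
    .default = readr::col_double()
  ))
  analytes <- if (!is.null(analytes_csv)) {
    strict_csv(analytes_csv, readr::cols(
      child_id = readr::col_character(),
      age = readr::col_double(),
      analyte = readr::col_character(),
      value = readr::col_double(),
      units = readr::col_character()
    ))
  }
  growth_cohort(children, observations, analytes)
}

strict_csv <- function(path, col_types) {
  out <- suppressWarnings(
    readr::read_csv(path, col_types = col_types, progress = FALSE)
  )
  pr <- readr::problems(out)
  if (nrow(pr)) {
    stop(
      "invalid values in ", path, ": ",
      paste(sprintf("row %d (%s)", pr$row, pr$expected), collapse = "; "),
      call. = FALSE
    )
  }
  out
}

#' @rdname read_cohort
#' @param cohort A [growth_cohort()].
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "growth_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$children, file.path(dir, "children.csv"))
  readr::write_csv(cohort$observations, file.path(dir, "observations.csv"))
  if (!is.null(cohort$analytes)) {
    readr::write_csv(cohort$analytes, file.path(dir, "analytes.csv"))
  }
  invisible(dir)
}

#' Run the full growth analysis on an annotated cohort
#'
#' Convenience wrapper chaining the pipeline stages: inclusion filters,
#' first-observation-per-age-group de-duplication, per-sex height contrasts
#' (SDS and cm) between two weight groups, growth-velocity computation and
#' contrasts (cm/year), cross-lagged BMI-to-height effects per sex, and the
#' piecewise random-intercept trend models. Individual stages are exported
#' separately; this wrapper fixes the conventional order.
#'
#' @param cohort An SDS-annotated [growth_cohort()] (see [reference_cohort()]).
#' @param reference Reference set (velocity SDS and mid-parental referencing).
#' @param group_a,group_b Weight groups contrasted (obese vs normal-weight).
#' @param min_n Minimum per-group stratum size.
#' @return A list of class `growth_analysis`: `exclusion_log`,
#'   `velocity_log`, `height_sds`, `height_cm`, `velocity` (tibbles with a
#'   `sex` column), `cross_lag`, `trends`, and row counts per stage.
#' @export
analyze_growth <- function(cohort, reference = default_reference(),
                           group_a = "obese", group_b = "normal",
                           min_n = 6) {
  stopifnot(inherits(cohort, "growth_cohort"))
  filt <- apply_inclusion_filters(cohort$observations, cohort$children)
  obs <- filt$observations
  first <- dedup_first_per_group(obs)

  per_sex <- function(data, value) {
    out <- dplyr::bind_rows(lapply(c("male", "female"), function(sx) {
      ds <- data[data$sex == sx, ]
      if (!nrow(ds)) {
        return(NULL)
      }
      dplyr::bind_cols(
        tibble::tibble(sex = sx),
        compare_groups(ds, value, "weight_category", group_a, group_b,
          min_n = min_n
        )
      )
    }))
    class(out) <- c("growth_comparison", class(out))
    out
  }

  vel <- compute_velocities(obs, velocity_reference = reference)
  pairs <- build_cross_lag_pairs(obs)
  cross <- dplyr::bind_rows(lapply(c("male", "female"), function(sx) {
    ps <- pairs[pairs$sex == sx, ]
    if (nrow(ps) < 3) {
      return(NULL)
    }
    dplyr::bind_cols(tibble::tibble(sex = sx), cross_lag_effect(ps))
  }))

  structure(
    list(
      exclusion_log = filt$log,
      velocity_log = vel$log,
      n_observations = nrow(obs),
      n_first_per_group = nrow(first),
      n_velocities = nrow(vel$velocities),
      height_sds = per_sex(first, "height_sds"),
      height_cm = per_sex(first, "height"),
      velocity = per_sex(vel$velocities, "gv"),
      cross_lag = cross,
      trends = piecewise_trend_analysis(obs, cohort$children)
    ),
    class = "growth_analysis"
  )
}

#' @export
print.growth_analysis <- function(x, ...) {
  cat("<growth_analysis>\n")
  cat(
    " observations retained:", x$n_observations,
    "| first-per-group:", x$n_first_per_group,
    "| velocity records:", x$n_velocities, "\n"
  )
  cat(
    " significant height-SDS strata:",
    sum(x$height_sds$significant, na.rm = TRUE), "\n"
  )
  invisible(x)
}

#' Write a JSON analysis report
#'
#' Aggregates the exclusion logs, per-stage row counts and all result tables
#' of a [analyze_growth()] run into one JSON document.
#'
#' @param analysis A `growth_analysis`.
#' @param path Output path.
#' @export
write_growth_report <- function(analysis, path) {
  payload <- list(
    exclusion_log = analysis$exclusion_log,
    velocity_log = analysis$velocity_log,
    counts = list(
      observations = analysis$n_observations,
      first_per_group = analysis$n_first_per_group,
      velocities = analysis$n_velocities
    ),
    height_sds = analysis$height_sds,
    height_cm = analysis$height_cm,
    velocity = analysis$velocity,
    cross_lag = analysis$cross_lag,
    trends = analysis$trends
  )
  jsonlite::write_json(payload, path,
    dataframe = "rows", auto_unbox = TRUE, digits = 6, pretty = TRUE
  )
  invisible(path)
}
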