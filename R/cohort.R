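# Cohort containers, SDS annotation, inclusion filters, age-group machinery.

#' Bundle cohort tables
#'
#' A growth cohort is a list of tidy tables: `children` (one row per child:
#' `id`, `sex`, `gestational_age_weeks`, `birth_length_cm`, `birth_weight_g`,
#' `mother_height_cm`, `father_height_cm`, `flags`), `observations` (one row
#' per visit: `child_id`, `age`, `height`, `weight`) and optionally
#' `analytes` (long format: `child_id`, `age`, `analyte`, `value`, `units`).
#'
#' @param children,observations,analytes Tibbles as described above.
#' @return A list of class `growth_cohort`.
#' @export
growth_cohort <- function(children, observations, analytes = NULL) {
  children <- tibble::as_tibble(children)
  observations <- tibble::as_tibble(observations)
  if (!"id" %in% names(children)) stop("`children` needs an `id` column", call. = FALSE)
  if (anyDuplicated(children$id)) stop("child ids must be unique", call. = FALSE)
  for (col in c("child_id", "age", "height", "weight")) {
    if (!col %in% names(observations)) {
      stop("`observations` needs a `", col, "` column", call. = FALSE)
    }
  }
  if (any(observations$age < 0, na.rm = TRUE)) {
    stop("observation ages must be >= 0", call. = FALSE)
  }
  ga <- children$gestational_age_weeks
  if (!is.null(ga) && any(!is.na(ga) & (ga < 22 | ga > 44))) {
    stop("gestational ages must lie in [22, 44] weeks", call. = FALSE)
  }
  structure(
    list(
      children = children,
      observations = observations,
      analytes = if (!is.null(analytes)) tibble::as_tibble(analytes)
    ),
    class = "growth_cohort"
  )
}

#' @export
print.growth_cohort <- function(x, ...) {
  cat(
    "<growth_cohort>", nrow(x$children), "children,",
    nrow(x$observations), "observations",
    if (!is.null(x$analytes)) paste0(", ", nrow(x$analytes), " analyte values"),
    "\n"
  )
  invisible(x)
}

#' Allocate an age to its age group
#'
#' Children are grouped by rounded age: group `g` covers `[g - 0.5, g + 0.5)`
#' years for `g = 1..17`, ages in `[0, 0.5)` form group 0, and everyone at or
#' above 17.5 years falls into the open-ended oldest group (printed "18+",
#' coded 18).
#'
#' @param age Age(s) in decimal years, `>= 0`.
#' @return Integer group codes 0..18; see [age_group_label()] for display.
#' @examples
#' assign_age_group(c(0.2, 0.5, 1.49, 1.5, 17.5, 19))
#' @export
assign_age_group <- function(age) {
  if (any(!is.finite(age) | age < 0)) {
    stop("ages must be finite and >= 0", call. = FALSE)
  }
  pmin(as.integer(floor(age + 0.5)), 18L)
}

#' @rdname assign_age_group
#' @param group Integer group codes as returned by `assign_age_group()`.
#' @export
age_group_label <- function(group) {
  ifelse(group >= 18, "18+", as.character(group))
}

#' Keep the first observation per child and age group
#'
#' Retains, for every (child, age group) cell, the row with the smallest age
#' (ties broken by input order); all other rows of that cell are dropped.
#' Stable and idempotent. Used both for cross-sectional height/analyte
#' contrasts and (with `age_col = "mean_age"`) for growth-velocity records.
#'
#' @param data Tibble with `child_id`, `age_group` and the age column.
#' @param age_col Name of the column holding the within-group ordering age.
#' @return The de-duplicated subset, in original row order.
#' @export
dedup_first_per_group <- function(data, age_col = "age") {
  stopifnot(all(c("child_id", "age_group", age_col) %in% names(data)))
  ord <- order(data$child_id, data$age_group, data[[age_col]], seq_len(nrow(data)))
  first <- !duplicated(data.frame(
    id = data$child_id[ord],
    g = data$age_group[ord]
  ))
  keep <- sort(ord[first])
  data[keep, ]
}

#' Annotate a cohort with reference SDS values
#'
#' Joins child sex onto observations, derives BMI (`weight[kg] / height[m]^2`),
#' computes height and BMI SDS against the supplied reference, classifies
#' weight status and age group per visit, and adds child-level derived fields
#' (mid-parental height SDS, birth length/weight SDS and SGA/AGA/LGA class).
#' Ages outside the tabulated reference range are referenced at the nearest
#' tabulated age (relevant only for the open-ended oldest group).
#'
#' @param cohort A [growth_cohort()].
#' @param reference An [lms_reference()] holding `height-for-age` and
#'   `bmi-for-age` (and, when birth columns are present,
#'   `birth-length-for-GA` / `birth-weight-for-GA`) measures.
#' @param weight_cutoffs,birth_cutoffs Cutoffs passed to [classify_weight()]
#'   and [classify_birth_size()].
#' @return The cohort with annotated `observations` and `children` tables.
#' @export
reference_cohort <- function(cohort, reference = default_reference(),
                             weight_cutoffs = c(-1.28, 1.28, 1.88),
                             birth_cutoffs = c(-1.28, 1.28)) {
  stopifnot(inherits(cohort, "growth_cohort"))
  obs <- cohort$observations
  kids <- cohort$children
  obs$sex <- kids$sex[match(obs$child_id, kids$id)]
  if (any(is.na(obs$sex))) {
    stop("observations reference unknown child ids", call. = FALSE)
  }
  obs$bmi <- obs$weight / (obs$height / 100)^2
  obs$height_sds <- clamped_sds(reference, obs$sex, obs$age, obs$height, "height-for-age")
  obs$bmi_sds <- clamped_sds(reference, obs$sex, obs$age, obs$bmi, "bmi-for-age")
  obs$weight_category <- classify_weight(obs$bmi_sds, weight_cutoffs)
  obs$age_group <- assign_age_group(obs$age)

  kids <- annotate_children(kids, reference, birth_cutoffs)
  cohort$observations <- obs
  cohort$children <- kids
  attr(cohort, "reference") <- unique(reference$measure)
  cohort
}

clamped_sds <- function(reference, sex, age, x, measure) {
  rng <- reference_range(reference, measure)
  lo <- rng$age_min[match(sex, rng$sex)]
  hi <- rng$age_max[match(sex, rng$sex)]
  reference_sds(reference, sex, pmin(pmax(age, lo), hi), x, measure)
}

annotate_children <- function(kids, reference, birth_cutoffs) {
  if (all(c("mother_height_cm", "father_height_cm") %in% names(kids))) {
    mp <- midparental_height_sds(
      kids$mother_height_cm, kids$father_height_cm, reference
    )
    kids$midparental_sds <- mp$midparental_sds
    kids$midparental_flag <- mp$flag
  }
  has_birth <- all(c("gestational_age_weeks", "birth_length_cm") %in% names(kids)) &&
    "birth-length-for-GA" %in% reference$measure
  if (has_birth) {
    kids$birth_length_sds <- birth_sds_at_ga(
      reference, kids$sex, kids$gestational_age_weeks, kids$birth_length_cm,
      "birth-length-for-GA"
    )
    if ("birth_weight_g" %in% names(kids) &&
      "birth-weight-for-GA" %in% reference$measure) {
      kids$birth_weight_sds <- birth_sds_at_ga(
        reference, kids$sex, kids$gestational_age_weeks, kids$birth_weight_g,
        "birth-weight-for-GA"
      )
    }
    kids$birth_size <- classify_birth_size(kids$birth_length_sds, birth_cutoffs)
  }
  kids
}

# birth references are tabulated against gestational age in weeks; children
# with unknown gestational age get NA (classification withheld, not an error)
birth_sds_at_ga <- function(reference, sex, ga_weeks, x, measure) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(ga_weeks) & !is.na(x) & x > 0
  if (any(ok)) {
    out[ok] <- reference_sds(reference, sex[ok], ga_weeks[ok], x[ok], measure)
  }
  out
}

#' Apply the cohort inclusion filters
#'
#' Drops observations that violate the plausibility and eligibility rules:
#' height SDS outside `[-2.5, 4.0]`; BMI SDS below `-3.5`; observations
#' before age 2.0 years from children born prematurely (gestational week
#' < 38, who are expected to have caught up in height by age 2); and all
#' observations of children flagged with a growth-affecting disease or
#' growth-affecting medication. Metformin/thyroxin flags are *not* applied
#' here: they restrict only the insulin/HOMA-IR and thyroid analyte analyses
#' (see [analyte_contrast()]).
#'
#' Each rule is a pure predicate on a row plus its child's attributes, so the
#' result is independent of rule order; the log counts how many rows each
#' rule hits (a row violating several rules is counted under each).
#'
#' @param observations SDS-annotated observations (see [reference_cohort()]).
#' @param children The cohort's children table.
#' @param height_sds_range,bmi_sds_min,premature_ga,premature_min_age Rule
#'   parameters, defaulting to the package's standard inclusion window.
#' @return A list: `observations` (retained rows) and `log` (tibble with
#'   columns `rule`, `n_excluded`, plus an `n_retained` attribute).
#' @export
apply_inclusion_filters <- function(observations, children,
                                    height_sds_range = c(-2.5, 4.0),
                                    bmi_sds_min = -3.5,
                                    premature_ga = 38,
                                    premature_min_age = 2.0) {
  if (!all(c("height_sds", "bmi_sds") %in% names(observations))) {
    stop("observations lack SDS columns; run reference_cohort() first",
      call. = FALSE
    )
  }
  idx <- match(observations$child_id, children$id)
  ga <- children$gestational_age_weeks[idx]
  flags <- children$flags[idx]
  rules <- list(
    height_sds_high = observations$height_sds > height_sds_range[2],
    height_sds_low = observations$height_sds < height_sds_range[1],
    bmi_sds_low = observations$bmi_sds < bmi_sds_min,
    premature_under_2y = !is.na(ga) & ga < premature_ga &
      observations$age < premature_min_age,
    disease_flag = has_flag(flags, "disease"),
    medication_flag = has_flag(flags, "medication")
  )
  rules <- lapply(rules, function(r) !is.na(r) & r)
  drop <- Reduce(`|`, rules)
  log <- tibble::tibble(
    rule = names(rules),
    n_excluded = unname(vapply(rules, sum, integer(1)))
  )
  attr(log, "n_retained") <- sum(!drop)
  list(observations = observations[!drop, ], log = log)
}

has_flag <- function(flags, what) {
  !is.na(flags) & vapply(
    strsplit(ifelse(is.na(flags), "", flags), ";", fixed = TRUE),
    function(f) what %in% trimws(f), logical(1)
  )
}
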