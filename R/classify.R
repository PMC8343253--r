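# Weight-status and birth-size classification from SDS values.

#' Classify weight status from BMI SDS
#'
#' Applies the pediatric consensus cutoff scheme: underweight below the lower
#' cutoff, normal-weight inside the closed interval, overweight above the
#' upper-normal cutoff up to and including the obesity cutoff, obesity
#' strictly above it. With the defaults: underweight `< -1.28`, normal
#' `[-1.28, 1.28]`, overweight `(1.28, 1.88]`, obese `> 1.88`.
#'
#' @param bmi_sds Finite BMI standard deviation score(s).
#' @param cutoffs Numeric `c(lower, upper_normal, obesity)` cutoffs.
#' @return Factor with levels `underweight`, `normal`, `overweight`, `obese`.
#' @examples
#' classify_weight(c(-1.29, -1.28, 1.28, 1.88, 1.881))
#' @export
classify_weight <- function(bmi_sds, cutoffs = c(-1.28, 1.28, 1.88)) {
  if (any(is.na(bmi_sds)) || any(!is.finite(bmi_sds))) {
    stop("`bmi_sds` must be finite and non-missing", call. = FALSE)
  }
  stopifnot(length(cutoffs) == 3, !is.unsorted(cutoffs))
  lev <- c("underweight", "normal", "overweight", "obese")
  out <- ifelse(bmi_sds < cutoffs[1], lev[1],
    ifelse(bmi_sds <= cutoffs[2], lev[2],
      ifelse(bmi_sds <= cutoffs[3], lev[3], lev[4])
    )
  )
  factor(out, levels = lev)
}

#' Classify birth size for gestational age
#'
#' Small / appropriate / large for gestational age (SGA/AGA/LGA) from a birth
#' size SDS computed against a gestational-age reference. Defaults use
#' +/- 1.28 SDS (about the 10th/90th centiles); the cutoffs are a package
#' convention, configurable by the caller.
#'
#' @param birth_sds Birth length or weight SDS; `NA` (e.g. gestational age
#'   unknown so no SDS could be computed) yields `NA` rather than an error.
#' @param cutoffs Numeric `c(lower, upper)`.
#' @return Factor with levels `SGA`, `AGA`, `LGA` (NA preserved).
#' @examples
#' classify_birth_size(c(-1.5, 0, 1.5))
#' @export
classify_birth_size <- function(birth_sds, cutoffs = c(-1.28, 1.28)) {
  stopifnot(length(cutoffs) == 2, cutoffs[1] < cutoffs[2])
  out <- ifelse(birth_sds < cutoffs[1], "SGA",
    ifelse(birth_sds > cutoffs[2], "LGA", "AGA")
  )
  factor(out, levels = c("SGA", "AGA", "LGA"))
}
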