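# Shared in-code fixtures for the unit tests.

# a minimal flat reference: height median 100 cm at every age, CV 5%,
# BMI median 16 with CV 10%, velocity median 6 cm/y with SD 1 cm/y
toy_reference <- function() {
  grid <- seq(0, 18, by = 1)
  rows <- lapply(c("male", "female"), function(sx) {
    dplyr::bind_rows(
      tibble::tibble(
        measure = "height-for-age", sex = sx, age = grid,
        L = 1, M = 100, S = 0.05
      ),
      tibble::tibble(
        measure = "bmi-for-age", sex = sx, age = grid,
        L = 1, M = 16, S = 0.10
      ),
      tibble::tibble(
        measure = "velocity-for-age", sex = sx, age = grid,
        L = 1, M = 6, S = 1 / 6
      ),
      tibble::tibble(
        measure = "birth-length-for-GA", sex = sx, age = 22:44,
        L = 1, M = 51 + 0.85 * (22:44 - 40), S = 2 / (51 + 0.85 * (22:44 - 40))
      )
    )
  })
  lms_reference(dplyr::bind_rows(rows))
}

# hand-built tiny cohort: heights chosen to give exact SDS against the toy
# reference (M = 100, S = 0.05 -> height = 100 * (1 + 0.05 * sds))
toy_children <- function(ids, ga = 40, flags = "") {
  tibble::tibble(
    id = ids, sex = "male",
    gestational_age_weeks = ga,
    birth_length_cm = 51, birth_weight_g = 3450,
    mother_height_cm = NA_real_, father_height_cm = NA_real_,
    flags = flags
  )
}

height_for_sds <- function(z) 100 * (1 + 0.05 * z)
weight_for_bmi_sds <- function(z, height_cm) {
  16 * (1 + 0.10 * z) * (height_cm / 100)^2
}

# small annotated observation table
toy_observations <- function(child_id, age, height_sds = 0, bmi_sds = 0) {
  h <- height_for_sds(height_sds)
  tibble::tibble(
    child_id = child_id, age = age,
    height = h, weight = weight_for_bmi_sds(bmi_sds, h)
  )
}
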