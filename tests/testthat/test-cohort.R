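test_that("age groups follow the rounded-age convention", {
  expect_equal(assign_age_group(c(0.5, 1.49, 1.5)), c(1L, 1L, 2L))
  expect_equal(assign_age_group(0.2), 0L)
  expect_equal(assign_age_group(c(17.49, 17.5, 19)), c(17L, 18L, 18L))
  expect_equal(age_group_label(assign_age_group(c(17.5, 19, 3))), c("18+", "18+", "3"))
  expect_error(assign_age_group(-0.1), ">= 0")
})

test_that("first-observation de-duplication keeps the youngest visit per cell", {
  obs <- tibble::tibble(
    child_id = c("a", "a", "a", "b"),
    age = c(6.4, 6.1, 7.1, 6.2),
    age_group = assign_age_group(c(6.4, 6.1, 7.1, 6.2))
  )
  kept <- dedup_first_per_group(obs)
  expect_equal(kept$age, c(6.1, 7.1, 6.2))
  # idempotent and stable
  expect_equal(dedup_first_per_group(kept), kept)
  # ties broken by input order
  tie <- tibble::tibble(
    child_id = "a", age = c(6.3, 6.3), age_group = 6L, tag = c("x", "y")
  )
  expect_equal(dedup_first_per_group(tie)$tag, "x")
})

test_that("reference annotation computes SDS, categories and age groups", {
  kids <- toy_children(c("a", "b"))
  obs <- dplyr::bind_rows(
    toy_observations("a", 4.0, height_sds = 1, bmi_sds = 0),
    toy_observations("b", 7.6, height_sds = -0.5, bmi_sds = 2.0)
  )
  coh <- reference_cohort(growth_cohort(kids, obs), toy_reference())
  o <- coh$observations
  expect_equal(o$height_sds, c(1, -0.5), tolerance = 1e-9)
  expect_equal(o$bmi_sds, c(0, 2.0), tolerance = 1e-9)
  expect_equal(as.character(o$weight_category), c("normal", "obese"))
  expect_equal(o$age_group, c(4L, 8L))
  expect_equal(coh$children$birth_length_sds, c(0, 0), tolerance = 1e-9)
})

test_that("inclusion filters implement the eligibility rules", {
  kids <- toy_children(c("k1", "k2", "k3", "k4"),
    ga = c(40, 36, 40, 40),
    flags = c("", "", "disease", "")
  )
  obs <- dplyr::bind_rows(
    toy_observations("k1", 5, height_sds = 4.2), # above the height window
    toy_observations("k1", 6, height_sds = 3.9), # retained
    toy_observations("k2", 1.5, height_sds = 0), # premature, under 2 y
    toy_observations("k2", 2.0, height_sds = 0), # retained from age 2
    toy_observations("k3", 5, height_sds = 0), # disease flag
    toy_observations("k4", 5, height_sds = -2.6) # below the height window
  )
  coh <- reference_cohort(growth_cohort(kids, obs), toy_reference())
  res <- apply_inclusion_filters(coh$observations, coh$children)
  expect_equal(sort(res$observations$age), c(2.0, 6))
  lg <- tibble::deframe(res$log)
  expect_equal(lg[["height_sds_high"]], 1L)
  expect_equal(lg[["height_sds_low"]], 1L)
  expect_equal(lg[["premature_under_2y"]], 1L)
  expect_equal(lg[["disease_flag"]], 1L)
  expect_equal(lg[["bmi_sds_low"]], 0L)
})

test_that("a clean cohort passes the filters with an all-zero log", {
  kids <- toy_children("c1")
  obs <- toy_observations("c1", c(3, 4), height_sds = c(0, 1))
  coh <- reference_cohort(growth_cohort(kids, obs), toy_reference())
  res <- apply_inclusion_filters(coh$observations, coh$children)
  expect_equal(nrow(res$observations), 2)
  expect_true(all(res$log$n_excluded == 0))
})

test_that("filters error without SDS annotation and ignore row order", {
  kids <- toy_children(c("k1", "k2"), ga = c(40, 36))
  obs <- dplyr::bind_rows(
    toy_observations("k1", 5, height_sds = 4.2),
    toy_observations("k2", 1.5),
    toy_observations("k2", 3),
    toy_observations("k1", 6)
  )
  expect_error(
    apply_inclusion_filters(obs, kids),
    "reference_cohort"
  )
  coh <- reference_cohort(growth_cohort(kids, obs), toy_reference())
  straight <- apply_inclusion_filters(coh$observations, coh$children)
  shuffled <- apply_inclusion_filters(coh$observations[c(3, 1, 4, 2), ], coh$children)
  expect_equal(
    dplyr::arrange(straight$observations, child_id, age),
    dplyr::arrange(shuffled$observations, child_id, age)
  )
  expect_equal(straight$log, shuffled$log)
})

test_that("metformin and thyroxin flags do not remove anthropometry", {
  kids <- toy_children(c("m1"), flags = "metformin;thyroxin")
  obs <- toy_observations("m1", 5)
  coh <- reference_cohort(growth_cohort(kids, obs), toy_reference())
  res <- apply_inclusion_filters(coh$observations, coh$children)
  expect_equal(nrow(res$observations), 1)
})
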