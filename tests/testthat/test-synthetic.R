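ref <- default_reference()
profile <- effect_profile()

test_that("the built-in reference hits its anchor points", {
  expect_equal(interpolate_lms(ref, "male", 0, "height-for-age")$M, 50)
  expect_equal(interpolate_lms(ref, "female", 8, "height-for-age")$M, 128)
  # a child exactly on the median has SDS 0 at every age
  for (t in c(0, 3.1, 9.7, 16.2)) {
    m <- interpolate_lms(ref, "male", t, "height-for-age")$M
    expect_equal(reference_sds(ref, "male", t, m, "height-for-age"), 0,
      tolerance = 1e-9
    )
  }
  # calibration: median x CV at the ages of maximal planted difference
  expect_equal(
    with(interpolate_lms(ref, "male", 6, "height-for-age"), M * S), 4.87,
    tolerance = 0.01
  )
  expect_equal(
    with(interpolate_lms(ref, "female", 8, "height-for-age"), M * S), 5.38,
    tolerance = 0.01
  )
})

test_that("the velocity reference integrates back to the height median", {
  for (sx in c("male", "female")) {
    grid <- seq(2, 17, by = 0.25)
    v <- interpolate_lms(ref, sx, grid, "velocity-for-age")$M
    m <- interpolate_lms(ref, sx, c(2, 17), "height-for-age")$M
    gained <- sum((v[-1] + v[-length(v)]) / 2 * diff(grid))
    expect_equal(gained, m[2] - m[1], tolerance = 0.2)
  }
})

test_that("the null profile produces an identically zero offset curve", {
  d0 <- build_obese_offset_curve(effect_profile(null = TRUE), "female", ref)
  expect_equal(d0(seq(0, 18, by = 0.5)), rep(0, 37))
})

test_that("the offset curve satisfies its construction constraints exactly", {
  for (sx in c("male", "female")) {
    d <- build_obese_offset_curve(profile, sx, ref)
    a <- profile$a_max[[sx]]
    expect_equal(d(a), profile$d_max[[sx]], tolerance = 1e-9)
    expect_equal(d(0), profile$birth_length_offset[[sx]])
    expect_lte(d(profile$convergence_age), 0.5)
    # obese/normal mean velocity over the group-aligned pubertal window
    w <- profile$pubertal_window[[sx]]
    lo <- w[1] - 0.5
    hi <- w[2] + 0.5
    m <- function(t) interpolate_lms(ref, sx, t, "height-for-age")$M
    ratio <- (m(hi) + d(hi) - m(lo) - d(lo)) / (m(hi) - m(lo))
    expect_equal(ratio, profile$pubertal_velocity_ratio[[sx]], tolerance = 0.01)
    # monotone rise to the maximum, monotone decline after the plateau
    rise <- d(seq(0.5, a, by = 0.1))
    expect_true(all(diff(rise) >= -1e-9))
  }
})

test_that("randomised feasible profiles keep the constraints", {
  set.seed(61)
  for (r in 1:8) {
    p <- effect_profile()
    sx <- sample(c("male", "female"), 1)
    p$d_max[sx] <- runif(1, 4.5, 7.5)
    p$birth_length_offset[sx] <- runif(1, 0, 0.8)
    p$pubertal_velocity_ratio[sx] <- runif(1, 0.8, 0.95)
    d <- build_obese_offset_curve(p, sx, ref)
    expect_equal(d(p$a_max[[sx]]), p$d_max[[sx]], tolerance = 1e-9)
    expect_lte(d(p$convergence_age), 0.5)
  }
  # infeasible: more offset than the velocity surplus can accumulate
  p <- effect_profile()
  p$d_max["male"] <- 12
  expect_error(
    build_obese_offset_curve(p, "male", ref),
    "attainable max"
  )
})

test_that("generation is deterministic given the seed and empty at n = 0", {
  cfg <- generator_config(n_normal = 40, n_obese = 40, seed = 9, with_analytes = TRUE)
  a <- generate_cohort(cfg, profile, ref)
  b <- generate_cohort(cfg, profile, ref)
  expect_identical(a$children, b$children)
  expect_identical(a$observations, b$observations)
  expect_identical(a$analytes, b$analytes)
  zero <- generate_cohort(
    generator_config(n_normal = 0, n_obese = 0), profile, ref
  )
  expect_equal(nrow(zero$children), 0)
  expect_equal(nrow(zero$observations), 0)
})

test_that("normal-stratum height SDS is standard normal across age bands", {
  coh <- reference_cohort(generate_cohort(
    generator_config(n_normal = 5000, n_obese = 0, seed = 10), profile, ref
  ), ref)
  obs <- coh$observations
  bands <- split(obs$height_sds, pmin(floor(obs$age / 3), 5))
  for (b in bands) {
    expect_gt(length(b), 500)
    expect_equal(mean(b), 0, tolerance = 0.05)
    expect_gte(stats::sd(b), 0.9)
    expect_lte(stats::sd(b), 1.1)
  }
})

test_that("normal-stratum velocities track the velocity reference median", {
  coh <- reference_cohort(generate_cohort(
    generator_config(n_normal = 4000, n_obese = 0, seed = 12), profile, ref
  ), ref)
  vel <- suppressWarnings(
    compute_velocities(coh$observations, velocity_reference = ref)
  )$velocities
  for (g in c(3, 5, 7, 9)) {
    v <- vel$gv[vel$age_group == g & vel$sex == "male"]
    med <- interpolate_lms(ref, "male", g, "velocity-for-age")$M
    expect_equal(mean(v), med, tolerance = 0.3)
  }
})

test_that("the default profile plants the qualitative growth pattern", {
  coh <- reference_cohort(generate_cohort(
    generator_config(n_normal = 1200, n_obese = 1200, seed = 13), profile, ref
  ), ref)
  first <- dedup_first_per_group(coh$observations)
  by_grp <- function(g, cat) {
    mean(first$height[first$age_group == g & first$weight_category == cat])
  }
  # taller at 6-8 years
  expect_gt(by_grp(7, "obese"), by_grp(7, "normal") + 3)
  vel <- compute_velocities(coh$observations, velocity_reference = ref)$velocities
  win <- vel[vel$age_group %in% 12:14, ]
  expect_lt(
    mean(win$gv[win$weight_category == "obese"]),
    mean(win$gv[win$weight_category == "normal"])
  )
})

test_that("stratum labels agree with the generated BMI SDS categories", {
  coh <- reference_cohort(generate_cohort(
    generator_config(n_normal = 300, n_obese = 300, seed = 14), profile, ref
  ), ref)
  obs <- coh$observations
  strat <- coh$children$stratum[match(obs$child_id, coh$children$id)]
  agree <- mean(as.character(obs$weight_category) == strat)
  expect_gt(agree, 0.99) # boundary rounding may flip a per-mille fraction
})
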