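test_that("mid-parental height SDS averages the parents' adult SDS", {
  ref <- default_reference() # adult medians 164 cm (female) / 177 cm (male)
  mo_m <- 164
  fa_m <- 177
  s <- 0.042
  at <- function(mo, fa) midparental_height_sds(mo, fa, ref)
  expect_equal(at(mo_m, fa_m)$midparental_sds, 0, tolerance = 1e-9)
  # both parents at +1 SDS -> mid-parental +1
  expect_equal(
    at(mo_m * (1 + s), fa_m * (1 + s))$midparental_sds, 1,
    tolerance = 1e-9
  )
  # mother +2, father 0 -> mean-of-SDS convention gives +1
  expect_equal(
    at(mo_m * (1 + 2 * s), fa_m)$midparental_sds, 1,
    tolerance = 1e-9
  )
  one <- at(mo_m * (1 + s), NA)
  expect_equal(one$midparental_sds, 1, tolerance = 1e-9)
  expect_equal(one$flag, "mother_only")
  none <- at(NA, 999) # implausible father treated as missing
  expect_true(is.na(none$midparental_sds))
  expect_equal(none$flag, "none")
})

test_that("height adjustment is linear and invertible", {
  child <- c(-1, 0, 2)
  mid <- c(0.5, -1, 1)
  adj <- adjust_height(child, mid)
  expect_equal(adj, child - mid)
  expect_equal(adj + mid, child)
  expect_equal(adjust_height(1, 1), 0)
})

test_that("cross-lag pairs use consecutive age groups, first visit per group", {
  obs <- tibble::tibble(
    child_id = c("a", "a", "b", "b", "c", "c", "c", "a"),
    age = c(3.1, 4.2, 3.0, 5.0, 3.2, 4.1, 5.3, 3.4),
    age_group = assign_age_group(c(3.1, 4.2, 3.0, 5.0, 3.2, 4.1, 5.3, 3.4)),
    bmi_sds = 1:8 / 10,
    height_sds = (1:8) / 20,
    sex = "male"
  )
  pairs <- build_cross_lag_pairs(obs)
  expect_equal(sort(pairs$age_group[pairs$child_id == "a"]), 3L)
  expect_equal(nrow(pairs[pairs$child_id == "b", ]), 0) # groups 3 and 5
  expect_equal(sort(pairs$age_group[pairs$child_id == "c"]), c(3L, 4L))
  # child a: the first group-3 visit (age 3.1) feeds the pair, not age 3.4
  expect_equal(pairs$bmi_sds_t[pairs$child_id == "a"], 0.1)
})

simulate_pairs <- function(n, beta, ar = 0.85, noise = 0.3, group = 1L) {
  bmi <- rnorm(n)
  h0 <- rnorm(n)
  h1 <- ar * h0 + beta * bmi + rnorm(n, 0, noise)
  tibble::tibble(
    child_id = as.character(seq_len(n)), age_group = group,
    bmi_sds_t = bmi, height_sds_t = h0,
    bmi_sds_t1 = 0.9 * bmi + rnorm(n, 0, 0.2), height_sds_t1 = h1
  )
}

test_that("cross-lag regression recovers a planted coefficient", {
  set.seed(21)
  pairs <- simulate_pairs(2000, beta = 0.18)
  est <- cross_lag_effect(pairs)
  expect_equal(est$beta, 0.18, tolerance = 0.03)
  expect_true(est$significant)
  expect_equal(est$n, 2000)
})

test_that("the null cross-lag coefficient is centred at zero", {
  set.seed(22)
  pairs <- dplyr::bind_rows(lapply(1:10, function(g) {
    simulate_pairs(500, beta = 0, group = g)
  }))
  est <- cross_lag_effect(pairs)
  expect_true(all(abs(est$beta) < 0.04))
  expect_lte(sum(est$significant), 3) # ~5% false positives expected
})

test_that("null cross-lag p-values are uniform on exchangeable data", {
  set.seed(23)
  p <- replicate(400, {
    cross_lag_effect(simulate_pairs(60, beta = 0))$p
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("the reversed direction and the singular design are handled", {
  set.seed(24)
  pairs <- simulate_pairs(500, beta = 0.2)
  rev <- cross_lag_effect(pairs, direction = "height_on_bmi")
  expect_true(is.finite(rev$beta))
  sing <- pairs
  sing$height_sds_t <- sing$bmi_sds_t # collinear predictor and outcome
  expect_error(cross_lag_effect(sing), "singular")
  # below the minimum group size nothing is fitted
  expect_equal(nrow(cross_lag_effect(pairs[1:2, ])), 0)
})

test_that("Holm-Sidak correction across ages is available for cross-lag", {
  set.seed(25)
  pairs <- dplyr::bind_rows(lapply(1:5, function(g) {
    simulate_pairs(100, beta = 0, group = g)
  }))
  raw <- cross_lag_effect(pairs)
  adj <- cross_lag_effect(pairs, correct = "holm_sidak")
  expect_true(all(adj$p >= raw$p - 1e-12))
})

balanced_ri_data <- function(n_subj, n_per, sigma_b, sigma_e, beta = c(1, 2)) {
  id <- rep(seq_len(n_subj), each = n_per)
  x <- rnorm(n_subj * n_per)
  b <- rnorm(n_subj, 0, sigma_b)[id]
  tibble::tibble(
    child_id = as.character(id), x = x,
    y = beta[1] + beta[2] * x + b + rnorm(length(id), 0, sigma_e)
  )
}

test_that("with no subject variance the fit reduces to OLS", {
  set.seed(31)
  d <- balanced_ri_data(100, 3, sigma_b = 0, sigma_e = 1)
  fit <- fit_random_intercept_lm(d, y ~ x)
  ols <- stats::lm(y ~ x, data = d)
  # the estimated variance ratio sits at (numerically near) the boundary,
  # where the GLS solution coincides with OLS
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-3)
  expect_lt(fit$sigma2_b, 0.05)
})

test_that("the REML fit equals brute-force GLS under the true covariance", {
  set.seed(32)
  n_subj <- 40
  n_per <- 3
  d <- balanced_ri_data(n_subj, n_per, sigma_b = 1, sigma_e = 0.5)
  fit <- fit_random_intercept_lm(d, y ~ x)
  # GLS at the *estimated* variance ratio, dense covariance, no shortcuts
  X <- cbind(1, d$x)
  V <- diag(nrow(d)) + fit$theta *
    outer(d$child_id, d$child_id, FUN = `==`)
  beta_gls <- unname(drop(solve(t(X) %*% solve(V, X), t(X) %*% solve(V, d$y))))
  expect_equal(fit$coefficients$estimate, beta_gls, tolerance = 1e-6)
})

test_that("variance components are recovered at scale", {
  set.seed(33)
  d <- balanced_ri_data(500, 4, sigma_b = sqrt(0.8), sigma_e = sqrt(0.2))
  fit <- fit_random_intercept_lm(d, y ~ x)
  expect_equal(fit$sigma2_b, 0.8, tolerance = 0.15) # relative +/-15%
  expect_equal(fit$sigma2_e, 0.2, tolerance = 0.15)
  expect_equal(fit$n_subjects, 500)
})

test_that("the returned variance ratio maximises the REML profile", {
  set.seed(34)
  d <- balanced_ri_data(80, 3, sigma_b = 0.9, sigma_e = 0.6)
  fit <- fit_random_intercept_lm(d, y ~ x)
  grid <- exp(seq(log(fit$theta / 10), log(fit$theta * 10), length.out = 21))
  expect_true(all(ri_reml_value(fit, fit$theta) >= ri_reml_value(fit, grid) - 1e-6))
})

test_that("the REML fit agrees with lme4 on fixed effects and variances", {
  set.seed(35)
  d <- balanced_ri_data(120, 4, sigma_b = 0.8, sigma_e = 0.5)
  fit <- fit_random_intercept_lm(d, y ~ x)
  lfit <- lme4::lmer(y ~ x + (1 | child_id), data = d, REML = TRUE)
  expect_equal(fit$coefficients$estimate, unname(lme4::fixef(lfit)),
    tolerance = 1e-4
  )
  vc <- as.data.frame(lme4::VarCorr(lfit))
  expect_equal(fit$sigma2_b, vc$vcov[1], tolerance = 1e-3)
  expect_equal(fit$sigma2_e, vc$vcov[2], tolerance = 1e-3)
})

test_that("rank-deficient designs and tiny cohorts raise errors", {
  d <- balanced_ri_data(10, 2, 0.5, 0.5)
  d$x2 <- d$x
  expect_error(fit_random_intercept_lm(d, y ~ x + x2), "aliased.*x2")
  d1 <- d[d$child_id == "1", ]
  expect_error(fit_random_intercept_lm(d1, y ~ x), "2 subjects")
})

trend_cohort <- function(n_per_group, slope_diff, seed,
                         interval = c(2, 4.99), n_visits = 3) {
  set.seed(seed)
  n <- 2 * n_per_group
  id <- sprintf("s%04d", seq_len(n))
  group <- rep(c("normal", "obese"), each = n_per_group)
  b <- rnorm(n, 0, 0.9)
  rows <- lapply(seq_len(n), function(i) {
    ages <- sort(runif(n_visits, interval[1], interval[2]))
    slope <- 0.05 + if (group[i] == "obese") slope_diff else 0
    tibble::tibble(
      child_id = id[i], sex = "male", age = ages,
      weight_category = group[i],
      height_sds = b[i] + slope * ages + rnorm(n_visits, 0, 0.2)
    )
  })
  dplyr::bind_rows(rows)
}

test_that("piecewise trends recover a planted slope difference", {
  obs <- trend_cohort(500, slope_diff = 0.15, seed = 41)
  res <- piecewise_trend_analysis(
    obs,
    intervals = tibble::tibble(
      sex = "male", interval = 1, age_lo = 2, age_hi = 4.99
    )
  )
  expect_equal(res$interaction, 0.15, tolerance = 0.05)
  expect_lt(res$p, 0.05)
  expect_equal(res$slope_b - res$slope_a, res$interaction)
})

test_that("a zero slope difference is rarely declared significant", {
  hits <- vapply(1:40, function(r) {
    obs <- trend_cohort(60, slope_diff = 0, seed = 100 + r)
    res <- piecewise_trend_analysis(
      obs,
      intervals = tibble::tibble(
        sex = "male", interval = 1, age_lo = 2, age_hi = 4.99
      )
    )
    res$p < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.15) # nominal 5%
})

test_that("independent covariates leave the slope contrast essentially unchanged", {
  obs <- trend_cohort(400, slope_diff = 0.15, seed = 43)
  kids <- tibble::tibble(
    id = unique(obs$child_id),
    midparental_sds = rnorm(length(unique(obs$child_id))),
    birth_length_sds = rnorm(length(unique(obs$child_id)))
  )
  iv <- tibble::tibble(sex = "male", interval = 1, age_lo = 2, age_hi = 4.99)
  plain <- piecewise_trend_analysis(obs, intervals = iv)
  adj <- piecewise_trend_analysis(obs, kids, intervals = iv, covariates = "adjusted")
  expect_lt(abs(adj$interaction - plain$interaction), plain$se)
})

test_that("interval boundaries match the quoted breakpoints", {
  iv <- default_age_intervals()
  boys <- iv[iv$sex == "male", ]
  expect_equal(boys$age_lo, c(2, 5, 11))
  expect_equal(boys$age_hi, c(4.99, 10.99, 17))
  girls <- iv[iv$sex == "female", ]
  expect_equal(girls$age_lo, c(2, 8.25, 11))
  # 4.99 and 5.0 land in different boys' intervals
  in1 <- boys$age_lo[1] <= 4.99 & 4.99 <= boys$age_hi[1]
  in2 <- boys$age_lo[2] <= 4.99 & 4.99 <= boys$age_hi[2]
  expect_true(in1)
  expect_false(in2)
  expect_true(boys$age_lo[2] <= 5.0 & 5.0 <= boys$age_hi[2])
})

test_that("tidy and glance expose the mixed-fit summaries", {
  set.seed(44)
  d <- balanced_ri_data(50, 3, 0.7, 0.5)
  fit <- fit_random_intercept_lm(d, y ~ x)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "x"))
  gl <- glance(fit)
  expect_true(all(c("sigma2_b", "sigma2_e", "reml_loglik") %in% names(gl)))
  expect_equal(gl$n_subjects, 50)
})
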