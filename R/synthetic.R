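# Synthetic cohort generator: reference-anchored height trajectories with a
# planted obesity effect profile, cross-lagged BMI-height dynamics, and
# endocrine age profiles. Everything is deterministic given the seed.

#' Built-in synthetic reference set
#'
#' A self-contained LMS reference table used as the default when no external
#' reference CSVs are supplied, and as the anchor of the synthetic cohort
#' generator. It holds `height-for-age` (Box-Cox L = 1, constant coefficient
#' of variation 0.042, median by monotone cubic interpolation through
#' sex-specific knots), `velocity-for-age` (median = the derivative of the
#' height median, reference SD fixed at 1 cm/year), `bmi-for-age`
#' (L = 1, S = 0.11 around a plausible BMI median curve), and birth length /
#' weight references linear in gestational age (SD 2 cm and 450 g; the `age`
#' column of those two measures is gestational age in weeks). The table is
#' synthetic: it mimics the shape of national growth references without
#' reproducing any published values.
#'
#' @param age_step Tabulation step in years for the age-based measures.
#' @return An [lms_reference()] table.
#' @export
default_reference <- function(age_step = 0.25) {
  knots_age <- c(0, 1, 2, 4, 6, 8, 10, 12, 14, 16, 18)
  knots_m <- list(
    male = c(50, 76, 88, 104, 116, 128, 139, 149, 163, 174, 177),
    female = c(49.5, 74.5, 86.5, 103, 115.5, 128, 139, 152, 160, 163.5, 164)
  )
  bmi_age <- c(0, 1, 2, 4, 6, 8, 10, 12, 14, 16, 18)
  bmi_m <- c(13.4, 17.2, 16.5, 15.7, 15.5, 16.0, 16.9, 17.8, 19.0, 20.2, 21.0)
  grid <- seq(0, 18, by = age_step)
  rows <- lapply(c("male", "female"), function(sx) {
    hf <- stats::splinefun(knots_age, knots_m[[sx]], method = "monoH.FC")
    m_h <- hf(grid)
    m_v <- pmax(hf(grid, deriv = 1), 0.1)
    bf <- stats::splinefun(bmi_age, bmi_m, method = "natural")
    dplyr::bind_rows(
      tibble::tibble(
        measure = "height-for-age", sex = sx, age = grid,
        L = 1, M = m_h, S = 0.042
      ),
      tibble::tibble(
        measure = "velocity-for-age", sex = sx, age = grid,
        L = 1, M = m_v, S = 1.0 / m_v
      ),
      tibble::tibble(
        measure = "bmi-for-age", sex = sx, age = grid,
        L = 1, M = bf(grid), S = 0.11
      )
    )
  })
  ga <- 22:44
  birth <- lapply(c("male", "female"), function(sx) {
    m_len <- 51 + 0.85 * (ga - 40) + if (sx == "male") 0.3 else 0
    m_wt <- 3450 + 170 * (ga - 40) + if (sx == "male") 60 else 0
    dplyr::bind_rows(
      tibble::tibble(
        measure = "birth-length-for-GA", sex = sx, age = ga,
        L = 1, M = m_len, S = 2 / m_len
      ),
      tibble::tibble(
        measure = "birth-weight-for-GA", sex = sx, age = ga,
        L = 1, M = m_wt, S = 450 / m_wt
      )
    )
  })
  lms_reference(
    dplyr::bind_rows(rows, birth),
    units = c(
      "height-for-age" = "cm", "velocity-for-age" = "cm/year",
      "bmi-for-age" = "kg/m2", "birth-length-for-GA" = "cm",
      "birth-weight-for-GA" = "g"
    )
  )
}

#' Planted obesity effect profile
#'
#' Parameterises every systematic difference the generator plants between the
#' obese and normal-weight strata: the mean height offset curve (maximal
#' difference `d_max` cm reached at age `a_max`, built from an early
#' velocity surplus of up to `delta_v_peak` cm/year), the blunted pubertal
#' spurt (obese/normal mean-velocity ratio over the sex-specific pubertal
#' window), convergence of the height curves by `convergence_age`, the
#' age-resolved cross-lag coefficient linking BMI SDS to next-year height
#' SDS, and multiplicative endocrine effects. `effect_profile(null = TRUE)`
#' zeroes every offset, sets all multipliers to 1 and the cross-lag to 0:
#' the exact no-effect configuration used for calibration runs.
#'
#' @param null Build the no-effect profile instead of the defaults.
#' @return A list of class `effect_profile`.
#' @export
effect_profile <- function(null = FALSE) {
  p <- list(
    birth_length_offset = c(male = 0.5, female = 0.7),
    d_max = c(male = 6.8, female = 7.6),
    a_max = c(male = 6, female = 8),
    delta_v_peak = 1.2,
    pubertal_window = list(male = c(13, 14), female = c(12, 13)),
    pubertal_velocity_ratio = c(male = 0.75, female = 0.78),
    convergence_age = 17,
    convergence_residual = 0.3,
    gamma_knots = list(
      male = cbind(age = c(1, 10.5, 14, 17), gamma = c(0.18, 0, -0.10, -0.06)),
      female = cbind(age = c(1, 9.5, 11, 17), gamma = c(0.18, 0, -0.10, -0.06))
    ),
    analytes = list(
      igf1_prepub = 1.10, igf1_prepub_window = c(6, 9), igf1_pub = 0.83,
      testosterone_pub = 0.38, testosterone_recovery = 0.9,
      testosterone_girls = 1.25,
      estradiol_late = 0.63, estradiol_window = c(15, 16),
      insulin = 2.5, leptin = 4
    )
  )
  if (null) {
    p$birth_length_offset[] <- 0
    p$d_max[] <- 0
    p$pubertal_velocity_ratio[] <- 1
    p$gamma_knots <- lapply(p$gamma_knots, function(k) {
      k[, "gamma"] <- 0
      k
    })
    p$analytes[c(
      "igf1_prepub", "igf1_pub", "testosterone_pub",
      "testosterone_recovery", "testosterone_girls",
      "estradiol_late", "insulin", "leptin"
    )] <- 1
  }
  structure(p, class = "effect_profile")
}

# age-resolved cross-lag coefficient gamma(t) for one sex
gamma_function <- function(profile, sex) {
  k <- profile$gamma_knots[[sex]]
  function(t) stats::approx(k[, "age"], k[, "gamma"], xout = t, rule = 2)$y
}

#' Mean height offset curve of the obese stratum
#'
#' Constructs the planted centimetre offset `D(t)` added to the obese
#' stratum's mean height: constant at the birth offset until 0.5 years, an
#' early-childhood velocity surplus (linear ramp to `delta_v_peak`, then a
#' plateau) whose ramp length is solved so that `D(a_max) = d_max` exactly, a
#' flat phase until the decline onset, a pubertal phase over the group-aligned
#' window `[w1 - 0.5, w2 + 0.5]` in which the obese mean velocity is exactly
#' `pubertal_velocity_ratio` times the reference velocity, and linear
#' catch-down on either side so that `D(convergence_age)` equals the small
#' configured residual. If `d_max` is too large to be reachable by `a_max`
#' at `delta_v_peak`, an error reports the attainable maximum; if it is too
#' small for a full-height ramp, a lower triangular surplus is used.
#'
#' @param profile An [effect_profile()].
#' @param sex `"male"` or `"female"`.
#' @param reference Reference set supplying the height median curve.
#' @return A vectorised function `D(t)` (cm) with the construction stored in
#'   `attr(, "pieces")`.
#' @export
build_obese_offset_curve <- function(profile, sex,
                                     reference = default_reference()) {
  d0 <- unname(profile$birth_length_offset[sex])
  dm <- unname(profile$d_max[sex])
  a <- unname(profile$a_max[sex])
  peak <- profile$delta_v_peak
  ratio <- unname(profile$pubertal_velocity_ratio[sex])
  w <- profile$pubertal_window[[sex]]
  conv <- profile$convergence_age
  d_end_target <- profile$convergence_residual

  m_at <- function(t) interpolate_lms(reference, sex, t, "height-for-age")$M

  if (dm == 0 && d0 == 0 && ratio == 1) {
    f <- function(t) rep(0, length(t))
    attr(f, "pieces") <- list(null = TRUE)
    return(f)
  }

  rise <- dm - d0
  if (rise < 0) stop("d_max must be >= the birth offset", call. = FALSE)
  attainable <- d0 + peak * (a - 0.5)
  if (dm > attainable) {
    stop(sprintf(
      "d_max %.2f cm not reachable by age %.2f at %.2f cm/year; attainable max %.2f cm",
      dm, a, peak, attainable
    ), call. = FALSE)
  }
  if (rise >= peak * (a - 0.5) / 2) {
    t1 <- 0.5 + 2 * ((a - 0.5) - rise / peak) # ramp end; plateau runs to a_max
    vpk <- peak
  } else {
    t1 <- a # pure triangle at a reduced peak
    vpk <- 2 * rise / (a - 0.5)
  }

  wlo <- w[1] - 0.5
  whi <- w[2] + 0.5
  s <- min(11, wlo) # decline onset
  if (s < a) stop("pubertal window overlaps the rise phase", call. = FALSE)
  drop_w <- (1 - ratio) * (m_at(whi) - m_at(wlo))
  if (dm - drop_w < 0) {
    stop("velocity-ratio constraint would drive the offset negative", call. = FALSE)
  }
  d_end <- min(d_end_target, dm - drop_w)
  r_rem <- dm - drop_w - d_end
  len_pre <- wlo - s
  len_post <- conv - whi
  rate <- if (len_pre + len_post > 0) r_rem / (len_pre + len_post) else 0

  d_wlo <- dm - rate * len_pre
  m_wlo <- m_at(wlo)
  d_whi <- d_wlo - drop_w

  f <- function(t) {
    out <- numeric(length(t))
    out[t <= 0.5] <- d0
    i <- t > 0.5 & t <= t1
    out[i] <- d0 + vpk * (t[i] - 0.5)^2 / (2 * (t1 - 0.5))
    i <- t > t1 & t <= a
    out[i] <- d0 + vpk * (t1 - 0.5) / 2 + vpk * (t[i] - t1)
    i <- t > a & t <= s
    out[i] <- dm
    i <- t > s & t <= wlo
    out[i] <- dm - rate * (t[i] - s)
    i <- t > wlo & t <= whi
    if (any(i)) out[i] <- d_wlo - (1 - ratio) * (m_at(t[i]) - m_wlo)
    i <- t > whi & t <= conv
    out[i] <- d_whi - rate * (t[i] - whi)
    out[t > conv] <- d_end
    out
  }
  attr(f, "pieces") <- list(
    d0 = d0, t1 = t1, vpk = vpk, a = a, s = s, wlo = wlo, whi = whi,
    conv = conv, rate = rate, d_end = d_end, drop_w = drop_w
  )
  f
}

#' Generator configuration
#'
#' Sampling design of the synthetic cohort: stratum sizes, the visit
#' schedule (first visit uniform in `first_age_range`, then annual visits
#' jittered by +/- `visit_jitter` years up to `max_age`, each non-initial
#' visit retained independently with probability `retention`), prematurity,
#' the latent height-SDS process (subject intercept SD, annual innovation
#' SD; the autoregression coefficient is derived so the marginal SD is
#' stationary), measurement error, stratum-specific BMI SDS distributions
#' (truncated normals with AR(1) persistence across visits), analyte noise,
#' and parental height coupling.
#'
#' @param n_normal,n_obese,n_underweight,n_overweight Children per stratum.
#' @param seed Integer seed; fully determines the cohort.
#' @param first_age_range,visit_jitter,retention,max_age Visit schedule.
#' @param premature_frac Fraction with gestational age < 38 weeks
#'   (drawn uniform 32-37).
#' @param intercept_sd,innovation_cm,meas_error_cm Latent height process and
#'   measurement error. The annual innovation of the latent height process is
#'   specified in centimetres (default 1.0 cm, the velocity reference SD) and
#'   converted to SDS at each age via the reference `M * S`, so that the
#'   year-to-year height fluctuation is consistent with the velocity
#'   reference at every age (about 0.3 SDS in infancy, less in adolescence).
#' @param bmi_ar AR(1) persistence of BMI SDS across visits.
#' @param analyte_cv Log-normal coefficient of variation of analyte values.
#' @param with_analytes Emit the endocrine panel.
#' @param parental_coupling,parental_sd Parent SDS = coupling x child
#'   intercept + N(0, parental_sd).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_normal = 1000, n_obese = 1000,
                             n_underweight = 0, n_overweight = 0,
                             seed = 1,
                             first_age_range = c(0.5, 4),
                             visit_jitter = 0.15,
                             retention = 0.8,
                             max_age = 18,
                             premature_frac = 0.08,
                             intercept_sd = 0.95,
                             innovation_cm = 1.0,
                             meas_error_cm = 0.3,
                             bmi_ar = 0.9,
                             analyte_cv = 0.35,
                             with_analytes = FALSE,
                             parental_coupling = 0.5,
                             parental_sd = 0.7) {
  if (innovation_cm <= 0 || intercept_sd <= 0) {
    stop("innovation_cm and intercept_sd must be positive", call. = FALSE)
  }
  structure(as.list(environment()), class = "generator_config")
}

# stratum-level BMI SDS distributions (mean, sd, truncation bounds). Bounds
# sit 0.01 SDS inside the category cutoffs so that the small BMI perturbation
# introduced by rounding emitted heights/weights cannot flip the category.
bmi_strata <- function() {
  list(
    underweight = list(mean = -1.6, sd = 0.25, lo = -3.4, hi = -1.29),
    normal = list(mean = 0, sd = 0.65, lo = -1.27, hi = 1.27),
    overweight = list(mean = 1.55, sd = 0.2, lo = 1.29, hi = 1.87),
    obese = list(mean = 2.4, sd = 0.35, lo = 1.89, hi = 5)
  )
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(
    n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd)
  )
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic cohort
#'
#' Simulates children and visits with the statistical structure the analysis
#' pipeline assumes: height trajectories anchored to the reference median
#' (individual intercept plus a stationary autoregressive annual process),
#' the planted obesity offset curve added to the obese stratum in
#' centimetres, cross-lagged coupling of next-year height SDS to the current
#' within-stratum BMI SDS deviation, stratum-specific truncated-normal BMI
#' SDS with AR(1) persistence across visits, parental heights correlated
#' with the child's height intercept, gestational-age-referenced birth size
#' (with the obese birth-length offset), and, optionally, an endocrine panel
#' (IGF-1, IGFBP-3, testosterone, estradiol, insulin, leptin, glucose) from
#' age/sex mean curves times planted stratum multipliers times log-normal
#' noise. Regenerating with the same config and profile is bit-identical.
#'
#' @param config A [generator_config()].
#' @param profile An [effect_profile()].
#' @param reference Reference set; also the anchor of all SDS plants.
#' @return A [growth_cohort()].
#' @export
generate_cohort <- function(config = generator_config(),
                            profile = effect_profile(),
                            reference = default_reference()) {
  set.seed(config$seed)
  strata <- bmi_strata()
  stratum <- rep(
    c("normal", "obese", "underweight", "overweight"),
    c(config$n_normal, config$n_obese, config$n_underweight, config$n_overweight)
  )
  n <- length(stratum)
  empty <- tibble::tibble(
    child_id = character(), age = numeric(), height = numeric(),
    weight = numeric()
  )
  if (n == 0) {
    return(growth_cohort(
      tibble::tibble(
        id = character(), sex = character(),
        gestational_age_weeks = numeric(), birth_length_cm = numeric(),
        birth_weight_g = numeric(), mother_height_cm = numeric(),
        father_height_cm = numeric(), flags = character()
      ),
      empty,
      if (config$with_analytes) {
        tibble::tibble(
          child_id = character(), age = numeric(),
          analyte = character(), value = numeric(), units = character()
        )
      }
    ))
  }

  id <- sprintf("C%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
  premature <- stats::runif(n) < config$premature_frac
  ga <- ifelse(premature, stats::runif(n, 32, 37), stats::runif(n, 38, 41.5))

  u <- stats::rnorm(n, 0, config$intercept_sd)

  # birth size, referenced to gestational age; obese get the planted offset
  b_sds <- 0.5 * u + stats::rnorm(n, 0, 0.88)
  len_lms <- interpolate_lms(reference, sex, ga, "birth-length-for-GA")
  birth_len <- value_from_sds(b_sds, len_lms$L, len_lms$M, len_lms$S) +
    unname(profile$birth_length_offset[sex]) * (stratum == "obese")
  bw_sds <- 0.7 * b_sds + stats::rnorm(n, 0, 0.71)
  wt_lms <- interpolate_lms(reference, sex, ga, "birth-weight-for-GA")
  birth_wt <- value_from_sds(bw_sds, wt_lms$L, wt_lms$M, wt_lms$S)

  mo_lms <- adult_lms(reference, "female", "height-for-age")
  fa_lms <- adult_lms(reference, "male", "height-for-age")
  mother <- value_from_sds(
    config$parental_coupling * u + stats::rnorm(n, 0, config$parental_sd),
    mo_lms$L, mo_lms$M, mo_lms$S
  )
  father <- value_from_sds(
    config$parental_coupling * u + stats::rnorm(n, 0, config$parental_sd),
    fa_lms$L, fa_lms$M, fa_lms$S
  )

  children <- tibble::tibble(
    id = id, sex = sex, stratum = stratum,
    gestational_age_weeks = round(ga, 1),
    birth_length_cm = round(birth_len, 1),
    birth_weight_g = round(birth_wt),
    mother_height_cm = round(mother, 1),
    father_height_cm = round(father, 1),
    flags = ""
  )

  # visit schedule: columns are annual visit slots
  j_max <- as.integer(ceiling(config$max_age - config$first_age_range[1])) + 1L
  ages <- matrix(NA_real_, n, j_max)
  ages[, 1] <- stats::runif(n, config$first_age_range[1], config$first_age_range[2])
  for (j in 2:j_max) {
    ages[, j] <- ages[, j - 1] +
      1 + stats::runif(n, -config$visit_jitter, config$visit_jitter)
  }
  scheduled <- ages <= config$max_age
  retained <- matrix(stats::runif(n * j_max) < config$retention, n, j_max)
  retained[, 1] <- TRUE
  keep <- scheduled & retained

  # latent BMI SDS path per stratum (truncated normal, AR(1) across visits)
  sp <- strata[stratum]
  mu <- vapply(sp, `[[`, numeric(1), "mean")
  sdv <- vapply(sp, `[[`, numeric(1), "sd")
  lo <- vapply(sp, `[[`, numeric(1), "lo")
  hi <- vapply(sp, `[[`, numeric(1), "hi")
  bmi <- matrix(NA_real_, n, j_max)
  bmi[, 1] <- rtrunc_norm(n, mu, sdv, lo, hi)
  sd_inn_b <- sdv * sqrt(1 - config$bmi_ar^2)
  for (j in 2:j_max) {
    prop <- mu + config$bmi_ar * (bmi[, j - 1] - mu) +
      stats::rnorm(n, 0, sd_inn_b)
    bmi[, j] <- pmin(pmax(prop, lo), hi)
  }

  # latent height SDS: stationary AR around 0 with cross-lag coupling to the
  # within-stratum BMI deviation (the planted, recoverable coefficient).
  # The annual innovation is innovation_cm expressed in SDS at the visit age,
  # and the AR coefficient is solved per step so Var(h) stays at
  # intercept_sd^2 across age.
  gam <- list(
    male = gamma_function(profile, "male"),
    female = gamma_function(profile, "female")
  )
  h <- matrix(NA_real_, n, j_max)
  h[, 1] <- u
  is_m <- sex == "male"
  for (j in 2:j_max) {
    g_j <- numeric(n)
    g_j[is_m] <- gam$male(ages[is_m, j - 1])
    g_j[!is_m] <- gam$female(ages[!is_m, j - 1])
    ms <- interpolate_lms(
      reference, sex, pmin(ages[, j], config$max_age), "height-for-age"
    )
    inn_sds <- pmin(config$innovation_cm / (ms$M * ms$S),
      0.9 * config$intercept_sd
    )
    a_h <- sqrt(1 - (inn_sds / config$intercept_sd)^2)
    h[, j] <- a_h * h[, j - 1] + g_j * (bmi[, j - 1] - mu) +
      stats::rnorm(n, 0, inn_sds)
  }

  d_curve <- list(
    male = build_obese_offset_curve(profile, "male", reference),
    female = build_obese_offset_curve(profile, "female", reference)
  )

  vis <- which(keep, arr.ind = TRUE)
  vis <- vis[order(vis[, 1], vis[, 2]), , drop = FALSE]
  ci <- vis[, 1]
  age_v <- ages[vis]
  h_v <- h[vis]
  bmi_v <- bmi[vis]
  lms_h <- interpolate_lms(reference, sex[ci], age_v, "height-for-age")
  height <- value_from_sds(h_v, lms_h$L, lms_h$M, lms_h$S) +
    stats::rnorm(length(ci), 0, config$meas_error_cm)
  ob <- stratum[ci] == "obese"
  height[ob & is_m[ci]] <- height[ob & is_m[ci]] + d_curve$male(age_v[ob & is_m[ci]])
  height[ob & !is_m[ci]] <- height[ob & !is_m[ci]] +
    d_curve$female(age_v[ob & !is_m[ci]])
  lms_b <- interpolate_lms(reference, sex[ci], age_v, "bmi-for-age")
  bmi_val <- value_from_sds(bmi_v, lms_b$L, lms_b$M, lms_b$S)
  weight <- bmi_val * (height / 100)^2

  observations <- tibble::tibble(
    child_id = id[ci],
    age = round(age_v, 3),
    height = round(height, 1),
    weight = round(weight, 2)
  )

  analytes <- NULL
  if (config$with_analytes) {
    analytes <- simulate_analytes(
      id[ci], sex[ci], stratum[ci], age_v, profile, config$analyte_cv
    )
  }

  out <- growth_cohort(children, observations, analytes)
  attr(out, "config") <- config
  attr(out, "profile") <- profile
  out
}

# ---- endocrine panel ------------------------------------------------------

# age/sex mean concentration curves: plausible textbook shapes, not fitted to
# any published figure
analyte_mean <- function(analyte, sex, age) {
  logistic <- function(t, lo, hi, mid, scale) {
    lo + (hi - lo) / (1 + exp(-(t - mid) / scale))
  }
  pw <- function(t, ka, kv) stats::approx(ka, kv, xout = t, rule = 2)$y
  switch(analyte,
    "IGF-1" = ifelse(sex == "male",
      pw(age, c(0, 5, 10, 13.5, 16, 18), c(50, 150, 260, 380, 300, 250)),
      pw(age, c(0, 5, 10, 12.5, 15, 18), c(55, 170, 300, 420, 320, 240))
    ),
    "IGFBP-3" = pw(age, c(0, 10, 13, 18), c(1.8, 4.2, 5.0, 4.5)),
    "testosterone" = ifelse(sex == "male",
      logistic(age, 0.5, 18, 13.5, 0.8),
      logistic(age, 0.3, 1.2, 12, 1.5)
    ),
    "estradiol" = ifelse(sex == "male", 25, logistic(age, 20, 350, 12.5, 0.9)),
    "insulin" = 30 + 3 * age,
    "leptin" = 2 + 0.4 * age,
    "glucose" = 4.6 + 0.02 * age,
    stop("unknown analyte: ", analyte, call. = FALSE)
  )
}

# obese-stratum multiplier, aligned to age-group boundaries so that the
# group means carry the planted effect exactly
analyte_multiplier <- function(analyte, sex, age, profile) {
  an <- profile$analytes
  pw <- profile$pubertal_window[[if (length(sex) == 1) sex else sex[1]]]
  out <- rep(1, length(age))
  m_sex <- sex == "male"
  win <- function(w) age >= w[1] - 0.5 & age < w[2] + 0.5
  if (analyte == "IGF-1") {
    iw <- an$igf1_prepub_window
    out[win(iw)] <- an$igf1_prepub
    for (sx in c("male", "female")) {
      w <- profile$pubertal_window[[sx]]
      sel <- (sex == sx) & win(w)
      out[sel] <- an$igf1_pub
    }
  } else if (analyte == "testosterone") {
    w <- profile$pubertal_window[["male"]]
    inw <- m_sex & win(w)
    out[inw] <- an$testosterone_pub
    rec <- m_sex & age >= w[2] + 0.5
    out[rec] <- pmin(
      an$testosterone_recovery,
      an$testosterone_pub + (an$testosterone_recovery - an$testosterone_pub) *
        (age[rec] - (w[2] + 0.5)) / max(17 - (w[2] + 0.5), 0.5)
    )
    out[!m_sex & age >= 8] <- an$testosterone_girls
  } else if (analyte == "estradiol") {
    sel <- !m_sex & win(an$estradiol_window)
    out[sel] <- an$estradiol_late
  } else if (analyte == "insulin") {
    out[] <- an$insulin
  } else if (analyte == "leptin") {
    out[] <- an$leptin
  }
  out
}

analyte_units <- c(
  "IGF-1" = "ng/mL", "IGFBP-3" = "ug/mL", "testosterone" = "nmol/L",
  "estradiol" = "pmol/L", "insulin" = "pmol/L", "leptin" = "ug/L",
  "glucose" = "mmol/L"
)

simulate_analytes <- function(child_id, sex, stratum, age, profile, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rows <- lapply(names(analyte_units), function(an) {
    cv_an <- if (an == "glucose") 0.06 else cv
    sdl <- sqrt(log(1 + cv_an^2))
    mult <- rep(1, length(age))
    ob <- stratum == "obese"
    if (any(ob)) {
      mult[ob] <- analyte_multiplier(an, sex[ob], age[ob], profile)
    }
    mu <- analyte_mean(an, sex, age) * mult
    tibble::tibble(
      child_id = child_id,
      age = round(age, 3),
      analyte = an,
      value = round(mu * stats::rlnorm(length(age), -sdl^2 / 2, sdl), 3),
      units = unname(analyte_units[an])
    )
  })
  dplyr::bind_rows(rows)
}
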