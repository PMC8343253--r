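# Regression machinery: mid-parental height adjustment, cross-lagged
# BMI -> height effects, random-intercept mixed fits, piecewise trends.

#' Mid-parental height SDS
#'
#' References each parent's adult height against the adult (oldest tabulated)
#' end of the sex-specific height reference and averages the two SDS values.
#' Averaging in SDS space already normalises for parental sex, so no
#' child-sex centimetre correction is applied (a cm-space mid-parental target
#' is deliberately not the package convention). With one parent missing the
#' available parent's SDS is used and flagged; with both missing the result
#' is `NA` ("none").
#'
#' @param mother_cm,father_cm Adult heights in cm; values outside
#'   `[120, 220]` cm are treated as missing.
#' @param reference An [lms_reference()] with a `height-for-age` measure.
#' @return Tibble with `midparental_sds` and `flag`
#'   (`both` / `mother_only` / `father_only` / `none`).
#' @export
midparental_height_sds <- function(mother_cm, father_cm,
                                   reference = default_reference()) {
  plaus <- function(x) ifelse(!is.na(x) & x >= 120 & x <= 220, x, NA_real_)
  mo <- plaus(mother_cm)
  fa <- plaus(father_cm)
  n <- max(length(mo), length(fa))
  mo <- rep_len(mo, n)
  fa <- rep_len(fa, n)
  mo_sds <- fa_sds <- rep(NA_real_, n)
  f_lms <- adult_lms(reference, "female", "height-for-age")
  m_lms <- adult_lms(reference, "male", "height-for-age")
  ok <- !is.na(mo)
  mo_sds[ok] <- sds(mo[ok], f_lms$L, f_lms$M, f_lms$S)
  ok <- !is.na(fa)
  fa_sds[ok] <- sds(fa[ok], m_lms$L, m_lms$M, m_lms$S)
  mid <- rowMeans(cbind(mo_sds, fa_sds), na.rm = TRUE)
  mid[is.na(mo_sds) & is.na(fa_sds)] <- NA_real_
  flag <- dplyr::case_when(
    !is.na(mo_sds) & !is.na(fa_sds) ~ "both",
    !is.na(mo_sds) ~ "mother_only",
    !is.na(fa_sds) ~ "father_only",
    .default = "none"
  )
  tibble::tibble(midparental_sds = mid, flag = flag)
}

#' Adjust a child's height SDS for familial height
#'
#' Subtracts the mid-parental height SDS, yielding height relative to the
#' familial expectation. Linear and invertible given the mid-parental SDS;
#' `NA` mid-parental values leave the adjustment withheld (`NA`).
#'
#' @param child_height_sds,midparental_sds Numeric vectors.
#' @return `child_height_sds - midparental_sds`.
#' @export
adjust_height <- function(child_height_sds, midparental_sds) {
  child_height_sds - midparental_sds
}

#' Build cross-lagged one-year observation pairs
#'
#' For each child and each consecutive age-group transition (g, g+1), pairs
#' the child's first observation in group g with its first observation in
#' group g+1. Children lacking the next group contribute nothing; a child
#' observed in groups 3, 4, 5 yields pairs at t = 3 and t = 4. The open-ended
#' oldest group is never a starting point.
#'
#' @param observations SDS-annotated observations with `age_group`.
#' @return Tibble: `child_id`, `age_group` (the t side), `bmi_sds_t`,
#'   `height_sds_t`, `bmi_sds_t1`, `height_sds_t1`.
#' @export
build_cross_lag_pairs <- function(observations) {
  stopifnot(all(c("child_id", "age_group", "bmi_sds", "height_sds") %in%
    names(observations)))
  first <- dedup_first_per_group(observations)
  key_t1 <- paste(first$child_id, first$age_group - 1L)
  key_t <- paste(first$child_id, first$age_group)
  nxt <- match(key_t, key_t1)
  has <- !is.na(nxt) & first$age_group < 18L
  tibble::tibble(
    child_id = first$child_id[has],
    sex = if ("sex" %in% names(first)) first$sex[has] else NA_character_,
    age_group = first$age_group[has],
    bmi_sds_t = first$bmi_sds[has],
    height_sds_t = first$height_sds[has],
    bmi_sds_t1 = first$bmi_sds[nxt[has]],
    height_sds_t1 = first$height_sds[nxt[has]]
  )
}

#' Cross-lagged effect of BMI SDS on next-year height SDS
#'
#' Per age group t, ordinary least squares of the outcome at t+1 on the
#' predictor at t, adjusted for the outcome at t. The default direction
#' regresses `height_sds_t1` on `{1, bmi_sds_t, height_sds_t}` and reports
#' the BMI coefficient (units: height SDS per BMI SDS). `direction =
#' "height_on_bmi"` swaps the roles. Significance is judged on the raw
#' two-sided p at `alpha` (per-age marking, no multiplicity correction by
#' default); `correct = "holm_sidak"` adjusts across the fitted ages.
#'
#' @param pairs Output of [build_cross_lag_pairs()].
#' @param direction Which variable leads.
#' @param min_n Minimum pairs per fitted age group (default 3).
#' @param alpha Significance level.
#' @param correct `"none"` or `"holm_sidak"`.
#' @return Tibble: `age_group`, `beta`, `se`, `p`, `n`, `significant`.
#' @export
cross_lag_effect <- function(pairs, direction = c("bmi_on_height", "height_on_bmi"),
                             min_n = 3, alpha = 0.05,
                             correct = c("none", "holm_sidak")) {
  direction <- match.arg(direction)
  correct <- match.arg(correct)
  if (direction == "bmi_on_height") {
    y1 <- pairs$height_sds_t1
    x <- pairs$bmi_sds_t
    y0 <- pairs$height_sds_t
  } else {
    y1 <- pairs$bmi_sds_t1
    x <- pairs$height_sds_t
    y0 <- pairs$bmi_sds_t
  }
  groups <- sort(unique(pairs$age_group))
  rows <- lapply(groups, function(g) {
    in_g <- pairs$age_group == g & !is.na(y1) & !is.na(x) & !is.na(y0)
    n <- sum(in_g)
    if (n < min_n) {
      return(NULL)
    }
    X <- cbind(1, x[in_g], y0[in_g])
    if (qr(X)$rank < 3L) {
      stop("singular cross-lag design in age group ", g,
        " (predictor and outcome at t are collinear)",
        call. = FALSE
      )
    }
    fit <- stats::lm.fit(X, y1[in_g])
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / (n - 3)
    xtxi <- chol2inv(chol(crossprod(X)))
    se <- sqrt(sigma2 * xtxi[2, 2])
    beta <- unname(fit$coefficients[2])
    tstat <- beta / se
    tibble::tibble(
      age_group = g, beta = beta, se = se,
      p = 2 * stats::pt(-abs(tstat), df = n - 3), n = n
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble::tibble(
      age_group = integer(), beta = numeric(), se = numeric(),
      p = numeric(), n = integer(), significant = logical()
    ))
  }
  if (correct == "holm_sidak") {
    out$p <- holm_sidak(out$p)
  }
  out$significant <- out$p < alpha
  out
}

#' Random-intercept linear model by REML
#'
#' Fits `y = X beta + b_subject + e` with `b ~ N(0, sigma2_b)` i.i.d. per
#' subject and `e ~ N(0, sigma2_e)`, by profiling the REML criterion over
#' the single variance ratio `theta = sigma2_b / sigma2_e` (1-D optimisation
#' on the log scale; generalised-least-squares closed form for `beta` given
#' `theta`). Deterministic; the boundary `theta -> 0` (plain OLS) is allowed.
#'
#' @param data Data frame holding the model variables.
#' @param formula Fixed-effects formula, e.g. `height_sds ~ age * group`.
#' @param subject Name of the subject-id column (the random intercept
#'   grouping).
#' @return An object of class `ri_fit` with [tidy()][tidy.ri_fit] and
#'   [glance()][glance.ri_fit] methods: fixed effects with SEs and Wald
#'   t-tests, `sigma2_b`, `sigma2_e`, the REML log-likelihood and sizes.
#' @export
fit_random_intercept_lm <- function(data, formula, subject = "child_id") {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  keep <- as.integer(rownames(mf))
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  id <- data[[subject]][keep]
  if (length(unique(id)) < 2) stop("need at least 2 subjects", call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    stop("rank-deficient fixed-effect design; aliased: ",
      paste(colnames(X)[qrx$pivot[-seq_len(qrx$rank)]], collapse = ", "),
      call. = FALSE
    )
  }
  fit <- ri_profile_fit(y, X, id)
  fit$call <- match.call()
  fit
}

# profiled REML machinery, shared with the criterion-evaluation helper
ri_suffstats <- function(y, X, id) {
  id <- as.character(id)
  G <- rowsum(cbind(X, y), id) # group sums of (X, y)
  list(
    XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y^2),
    SX = G[, -ncol(G), drop = FALSE], Sy = G[, ncol(G)],
    nvec = as.vector(table(id)[rownames(G)]),
    n = length(y), p = ncol(X), terms = colnames(X)
  )
}

ri_reml <- function(ss, theta) {
  ci <- theta / (1 + ss$nvec * theta)
  XtWX <- ss$XtX - crossprod(ss$SX, ss$SX * ci)
  XtWy <- ss$Xty - crossprod(ss$SX, ss$Sy * ci)
  ytWy <- ss$yty - sum(ci * ss$Sy^2)
  R <- chol(XtWX)
  beta <- backsolve(R, forwardsolve(t(R), XtWy))
  rss <- ytWy - sum(XtWy * beta)
  df <- ss$n - ss$p
  sigma2 <- rss / df
  logdetV <- sum(log1p(ss$nvec * theta))
  logdetXtWX <- 2 * sum(log(diag(R)))
  reml <- -0.5 * (df * log(2 * pi * sigma2) + logdetV + logdetXtWX + df)
  list(
    reml = reml, beta = drop(beta), sigma2 = sigma2,
    cov_beta = sigma2 * chol2inv(R)
  )
}

ri_profile_fit <- function(y, X, id) {
  ss <- ri_suffstats(y, X, id)
  obj <- function(lt) ri_reml(ss, exp(lt))$reml
  opt <- stats::optimize(obj, interval = c(log(1e-10), log(1e6)), maximum = TRUE)
  theta <- exp(opt$maximum)
  # boundary check: a ratio this small is numerically the OLS limit
  at0 <- ri_reml(ss, 0)
  if (at0$reml >= opt$objective) theta <- 0
  sol <- ri_reml(ss, theta)
  se <- sqrt(diag(sol$cov_beta))
  tstat <- sol$beta / se
  df <- ss$n - ss$p
  structure(
    list(
      coefficients = tibble::tibble(
        term = ss$terms, estimate = sol$beta, se = se,
        statistic = tstat, p = 2 * stats::pt(-abs(tstat), df = df)
      ),
      theta = theta,
      sigma2_e = sol$sigma2,
      sigma2_b = theta * sol$sigma2,
      reml_loglik = sol$reml,
      n_obs = ss$n,
      n_subjects = length(ss$nvec),
      suffstats = ss
    ),
    class = "ri_fit"
  )
}

#' Evaluate the profiled REML criterion of a fit at another variance ratio
#'
#' Mainly for diagnostics: the returned fit's `theta` maximises this curve.
#'
#' @param fit An `ri_fit`.
#' @param theta Variance ratio `sigma2_b / sigma2_e` (>= 0).
#' @return REML log-likelihood value(s).
#' @export
ri_reml_value <- function(fit, theta) {
  vapply(theta, function(th) ri_reml(fit$suffstats, th)$reml, numeric(1))
}

#' @export
print.ri_fit <- function(x, ...) {
  cat("Random-intercept linear model (REML)\n")
  cat(sprintf(
    "  %d obs, %d subjects; sigma2_b = %.4g, sigma2_e = %.4g\n",
    x$n_obs, x$n_subjects, x$sigma2_b, x$sigma2_e
  ))
  print(x$coefficients)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Broom-style accessors for `ri_fit` objects
#'
#' @param x An `ri_fit` object.
#' @param ... Unused.
#' @return `tidy()` returns the fixed-effect table (term, estimate, se,
#'   statistic, p); `glance()` a one-row model summary.
#' @export
tidy.ri_fit <- function(x, ...) x$coefficients

#' @rdname tidy.ri_fit
#' @export
glance.ri_fit <- function(x, ...) {
  tibble::tibble(
    sigma2_b = x$sigma2_b, sigma2_e = x$sigma2_e, theta = x$theta,
    reml_loglik = x$reml_loglik, n_obs = x$n_obs, n_subjects = x$n_subjects
  )
}

#' Default piecewise age intervals
#'
#' Three intervals of approximately linear height-SDS-versus-age trend,
#' sex-specific: boys 2.0-4.99, 5.0-10.99, 11.0-17.0 years; girls 2.0-8.249,
#' 8.25-10.99, 11.0-17.0 years.
#'
#' @return Tibble with `sex`, `interval`, `age_lo`, `age_hi`.
#' @export
default_age_intervals <- function() {
  tibble::tibble(
    sex = rep(c("male", "female"), each = 3),
    interval = rep(1:3, 2),
    age_lo = c(2.0, 5.0, 11.0, 2.0, 8.25, 11.0),
    age_hi = c(4.99, 10.99, 17.0, 8.249, 10.99, 17.0)
  )
}

#' Piecewise age-trend contrasts between weight groups
#'
#' Within each sex and age interval, fits a random-intercept model of height
#' SDS on age, weight group and their interaction; the interaction is the
#' difference in height-SDS-per-year slope between the groups (Wald test).
#' With `covariates = "adjusted"`, mid-parental height SDS and birth length
#' SDS enter as additive fixed effects (the reduced covariate model: birth
#' weight SDS and covariate interactions are deliberately not included).
#'
#' @param observations SDS-annotated observations (`height_sds`, `age`,
#'   `sex`, `weight_category`, `child_id`).
#' @param children Children table; required for `covariates = "adjusted"`
#'   (must carry `midparental_sds` and `birth_length_sds`, see
#'   [reference_cohort()]).
#' @param intervals As from [default_age_intervals()].
#' @param covariates `"none"` or `"adjusted"`.
#' @param groups Length-2 character: reference group then contrast group.
#' @param min_subjects Minimum subjects per group per interval; intervals
#'   below it are skipped with a warning.
#' @return Tibble per sex and interval: group slopes, the slope difference
#'   (`interaction`) with SE and p, and the variance components.
#' @export
piecewise_trend_analysis <- function(observations, children = NULL,
                                     intervals = default_age_intervals(),
                                     covariates = c("none", "adjusted"),
                                     groups = c("normal", "obese"),
                                     min_subjects = 2) {
  covariates <- match.arg(covariates)
  obs <- observations[as.character(observations$weight_category) %in% groups, ]
  obs$group <- factor(as.character(obs$weight_category), levels = groups)
  if (covariates == "adjusted") {
    if (is.null(children) ||
      !all(c("midparental_sds", "birth_length_sds") %in% names(children))) {
      stop("`covariates = \"adjusted\"` needs children with midparental_sds ",
        "and birth_length_sds",
        call. = FALSE
      )
    }
    i <- match(obs$child_id, children$id)
    obs$midparental_sds <- children$midparental_sds[i]
    obs$birth_length_sds <- children$birth_length_sds[i]
  }
  form <- if (covariates == "adjusted") {
    height_sds ~ age * group + midparental_sds + birth_length_sds
  } else {
    height_sds ~ age * group
  }
  rows <- purrr::pmap(intervals, function(sex, interval, age_lo, age_hi) {
    d <- obs[obs$sex == sex & obs$age >= age_lo & obs$age <= age_hi, ]
    d <- d[stats::complete.cases(d[all.vars(form)]), ]
    n_sub <- table(factor(d$group[!duplicated(d$child_id)], levels = groups))
    if (any(n_sub < min_subjects)) {
      warning(sprintf(
        "interval %d (%s): fewer than %d subjects in a group; skipped",
        interval, sex, min_subjects
      ), call. = FALSE)
      return(NULL)
    }
    fit <- fit_random_intercept_lm(d, form, subject = "child_id")
    co <- fit$coefficients
    b_age <- co[co$term == "age", ]
    b_int <- co[grepl("^age:group", co$term), ]
    tibble::tibble(
      sex = sex, interval = interval, age_lo = age_lo, age_hi = age_hi,
      n_obs = fit$n_obs, n_children = fit$n_subjects,
      slope_a = b_age$estimate,
      slope_b = b_age$estimate + b_int$estimate,
      interaction = b_int$estimate, se = b_int$se, p = b_int$p,
      sigma2_b = fit$sigma2_b, sigma2_e = fit$sigma2_e
    )
  })
  dplyr::bind_rows(rows)
}
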