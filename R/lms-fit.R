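# Penalized maximum-likelihood fitting of smooth L(t), M(t), S(t) curves
# (Cole-Green backfitting on cubic B-splines with curvature penalties).

#' Configuration for LMS curve fitting
#'
#' The three curves are cubic B-spline expansions over age with a
#' second-derivative (curvature) penalty per curve. Smoothness is specified
#' as equivalent degrees of freedom (EDF); the corresponding penalty weight
#' is solved once at initialisation from the trace of the hat matrix. The
#' median curve conventionally gets more freedom than the power and
#' variation curves. `M` and `S` are modelled on the log scale (positivity
#' by construction); `L` on the natural scale.
#'
#' @param edf Named numeric: target EDF for `L`, `M`, `S`. The defaults give
#'   the median curve generous freedom (no age-axis transformation is used,
#'   so the strong infancy curvature of height medians must be carried by
#'   the spline itself) while keeping the power and variation curves stiff.
#' @param alpha Optional named numeric overriding the solved penalty weights
#'   directly (e.g. `c(M = 100)`); mostly for smoothing diagnostics.
#' @param n_knots Number of interior knots.
#' @param knot_placement `"sqrt"` (default) spaces interior knots evenly on
#'   the square-root-age scale, concentrating resolution in infancy where
#'   growth-curve curvature is largest; `"quantile"` uses empirical age
#'   quantiles.
#' @param age_grid Ages at which fitted curves are evaluated.
#' @param max_iter,tol Outer backfitting iterations and relative
#'   penalized-log-likelihood convergence tolerance.
#' @param min_points,min_ages Floors on the input: at least `min_points`
#'   observations spanning at least `min_ages` distinct ages.
#' @return A list of class `lms_fit_config`.
#' @export
lms_fit_config <- function(edf = c(L = 3, M = 18, S = 4),
                           n_knots = 20,
                           knot_placement = c("sqrt", "quantile"),
                           alpha = NULL,
                           age_grid = seq(0, 18, by = 0.25),
                           max_iter = 50, tol = 1e-7,
                           min_points = 50, min_ages = 5) {
  stopifnot(all(c("L", "M", "S") %in% names(edf)), tol > 0)
  knot_placement <- match.arg(knot_placement)
  structure(as.list(environment()), class = "lms_fit_config")
}

# cubic B-spline design over [lo, hi] with given interior knots
bspline_basis <- function(interior, lo, hi) {
  knots <- c(rep(lo, 4), interior, rep(hi, 4))
  p <- length(interior) + 4L
  list(knots = knots, p = p, lo = lo, hi = hi)
}

bspline_eval <- function(basis, t, deriv = 0) {
  t <- pmin(pmax(t, basis$lo), basis$hi)
  splines::splineDesign(basis$knots, t, ord = 4, derivs = deriv, outer.ok = TRUE)
}

# exact Gram matrix of second derivatives (piecewise linear, so Simpson is
# exact on each inter-knot interval)
bspline_penalty <- function(basis) {
  kn <- unique(basis$knots)
  omega <- matrix(0, basis$p, basis$p)
  for (k in seq_len(length(kn) - 1)) {
    a <- kn[k]
    b <- kn[k + 1]
    d2 <- splines::splineDesign(basis$knots, c(a + 1e-9 * (b - a), (a + b) / 2,
      b - 1e-9 * (b - a)
    ), ord = 4, derivs = 2)
    omega <- omega + (b - a) / 6 *
      (crossprod(d2[1, , drop = FALSE]) + 4 * crossprod(d2[2, , drop = FALSE]) +
        crossprod(d2[3, , drop = FALSE]))
  }
  (omega + t(omega)) / 2
}

# solve the penalty weight whose hat-matrix trace matches the EDF target
# edf(alpha) = sum_i 1 / (1 + alpha * d_i), with d_i the generalised
# eigenvalues of the penalty against the weighted information: numerically
# stable for any alpha, monotone decreasing
alpha_for_edf <- function(B, w, omega, edf_target) {
  btwb <- crossprod(B, B * w)
  btwb <- btwb + diag(1e-8 * mean(diag(btwb)), ncol(B))
  R <- chol(btwb)
  ri <- backsolve(R, diag(ncol(B)))
  d <- pmax(eigen(crossprod(ri, omega %*% ri), symmetric = TRUE)$values, 0)
  edf_at <- function(log_alpha) sum(1 / (1 + exp(log_alpha) * d))
  if (edf_target >= edf_at(-25)) {
    return(exp(-25))
  }
  if (edf_target <= edf_at(25)) {
    return(exp(25))
  }
  r <- stats::uniroot(function(la) edf_at(la) - edf_target,
    lower = -25, upper = 25, tol = 1e-6
  )
  exp(r$root)
}

#' Fit smooth LMS curves to age-measurement data
#'
#' Maximises the penalized Box-Cox normal log-likelihood
#' `sum(loglik_boxcox) - 0.5 * sum_c alpha_c * integral(c''(t)^2)` over the
#' spline coefficients of the three curves by cyclic quasi-Newton updates
#' (M, S, L in turn) with step halving, which makes the penalized
#' log-likelihood non-decreasing across iterations. Initialisation is
#' deterministic: `L = 1`, `M` a running-median smooth, `S` a running
#' coefficient-of-variation smooth — so the fit is reproducible given the
#' data and configuration. Sexes are fitted independently: pass one sex's
#' points per call.
#'
#' @param data Data frame with columns `age` and `value` (one row per
#'   observation; use [sample_one_per_child()] first when children have
#'   repeated visits).
#' @param sex Optional label stored on the fit (e.g. `"female"`).
#' @param config An [lms_fit_config()].
#' @return An object of class `lms_fit`: fitted `L`, `M`, `S` on
#'   `config$age_grid`, achieved EDFs, penalty weights, log-likelihood,
#'   convergence flag and iteration count. Non-convergence within
#'   `max_iter` is reported via `converged = FALSE`, not an error.
#' @export
fit_lms <- function(data, sex = NULL, config = lms_fit_config()) {
  age <- data$age
  x <- data$value
  ok <- is.finite(age) & is.finite(x) & x > 0
  age <- age[ok]
  x <- x[ok]
  if (length(x) < config$min_points) {
    stop("need at least ", config$min_points, " observations to fit LMS curves",
      call. = FALSE
    )
  }
  if (length(unique(age)) < config$min_ages) {
    stop("need at least ", config$min_ages, " distinct ages", call. = FALSE)
  }

  lo <- min(age)
  hi <- max(age)
  probs <- seq_len(config$n_knots) / (config$n_knots + 1)
  interior <- if (config$knot_placement == "sqrt") {
    lo + (hi - lo) * probs^1.5
  } else {
    unique(stats::quantile(age, probs, names = FALSE))
  }
  basis <- bspline_basis(interior, lo, hi)
  B <- bspline_eval(basis, age)
  omega <- bspline_penalty(basis)
  p <- basis$p

  # deterministic initialisation: L = 1, running median / running CV
  ord <- order(age)
  k <- min(length(x) - (1 - length(x) %% 2), max(21, 2 * floor(length(x) / 40) + 1))
  med <- stats::runmed(x[ord], k, endrule = "median")
  resid <- abs(x[ord] - med) * 1.4826
  cv <- stats::runmed(resid, k, endrule = "median") / pmax(med, 1e-8)
  ridge <- diag(1e-6, p)
  gam_m <- solve(crossprod(B[ord, ]) + ridge, crossprod(B[ord, ], log(pmax(med, 1e-8))))
  gam_s <- solve(crossprod(B[ord, ]) + ridge, crossprod(B[ord, ], log(pmax(cv, 5e-3))))
  gam_l <- rep(1, p) # B-splines sum to one, so this is exactly L = 1

  w0 <- rep(1, length(x))
  alpha <- c(
    L = alpha_for_edf(B, w0 * 7 * exp(2 * mean(B %*% gam_s)) / 4, omega, config$edf["L"]),
    M = alpha_for_edf(B, w0 / exp(2 * mean(B %*% gam_s)), omega, config$edf["M"]),
    S = alpha_for_edf(B, w0 * 2, omega, config$edf["S"])
  )
  if (!is.null(config$alpha)) { # explicit penalty-weight overrides
    alpha[names(config$alpha)] <- config$alpha
  }

  curves <- function(gl, gm, gs) {
    list(
      L = drop(B %*% gl),
      M = exp(drop(B %*% gm)),
      S = exp(drop(B %*% gs))
    )
  }
  penalty <- function(gl, gm, gs) {
    0.5 * (alpha[["L"]] * drop(crossprod(gl, omega %*% gl)) +
      alpha[["M"]] * drop(crossprod(gm, omega %*% gm)) +
      alpha[["S"]] * drop(crossprod(gs, omega %*% gs)))
  }
  pll <- function(gl, gm, gs) {
    cv <- curves(gl, gm, gs)
    if (any(!is.finite(cv$M)) || any(!is.finite(cv$S))) {
      return(-Inf)
    }
    z <- lms_z(x, cv$L, cv$M, cv$S)
    if (any(!is.finite(z))) {
      return(-Inf)
    }
    sum(cv$L * log(x / cv$M) - log(cv$S) - z^2 / 2) - penalty(gl, gm, gs)
  }

  # one penalized quasi-Newton update of a single curve, with step halving
  update_curve <- function(which, gl, gm, gs) {
    cv <- curves(gl, gm, gs)
    L <- cv$L
    M <- cv$M
    S <- cv$S
    r <- x / M
    u <- r^L
    z <- lms_z(x, L, M, S)
    if (which == "M") { # eta = log M
      g <- -L + z * u / S
      w <- pmax(u^2 / S^2, 0.1 / S^2)
      gam <- gm
    } else if (which == "S") { # eta = log S
      g <- z^2 - 1
      w <- rep(2, length(x))
      gam <- gs
    } else { # L on the natural scale; clamp L away from 0 in the 1/L terms
      lr <- log(r)
      Lc <- ifelse(abs(L) < 1e-4, ifelse(L < 0, -1e-4, 1e-4), L)
      g <- lr - z * (u * lr / (Lc * S) - z / Lc)
      w <- pmax(7 * S^2 / 4, 1e-6)
      gam <- gl
    }
    grad <- crossprod(B, g) - alpha[[which]] * (omega %*% gam)
    H <- crossprod(B, B * w) + alpha[[which]] * omega
    delta <- solve(H, grad)
    f0 <- pll(gl, gm, gs)
    step <- 1
    for (i in 1:30) {
      cand <- gam + step * delta
      f1 <- switch(which,
        M = pll(gl, cand, gs),
        S = pll(gl, gm, cand),
        L = pll(cand, gm, gs)
      )
      if (is.finite(f1) && f1 >= f0 - 1e-10) {
        return(list(gam = cand, f = f1))
      }
      step <- step / 2
    }
    list(gam = gam, f = f0) # no improving step found; keep the old curve
  }

  f_prev <- pll(gam_l, gam_m, gam_s)
  converged <- FALSE
  iter <- 0
  trace <- f_prev
  for (iter in seq_len(config$max_iter)) {
    up <- update_curve("M", gam_l, gam_m, gam_s)
    gam_m <- up$gam
    up <- update_curve("S", gam_l, gam_m, gam_s)
    gam_s <- up$gam
    up <- update_curve("L", gam_l, gam_m, gam_s)
    gam_l <- up$gam
    f_new <- up$f
    trace <- c(trace, f_new)
    if (abs(f_new - f_prev) <= config$tol * (abs(f_prev) + 1)) {
      converged <- TRUE
      f_prev <- f_new
      break
    }
    f_prev <- f_new
  }

  grid <- config$age_grid
  grid <- grid[grid >= lo - 1e-9 & grid <= hi + 1e-9]
  Bg <- bspline_eval(basis, grid)
  edf_at <- function(gam, which, w) {
    btwb <- crossprod(B, B * w)
    sum(diag(solve(btwb + alpha[[which]] * omega, btwb)))
  }
  cvg <- curves(gam_l, gam_m, gam_s)
  z_fin <- lms_z(x, cvg$L, cvg$M, cvg$S)

  structure(
    list(
      sex = sex,
      age_grid = grid,
      L = drop(Bg %*% gam_l),
      M = exp(drop(Bg %*% gam_m)),
      S = exp(drop(Bg %*% gam_s)),
      coefficients = list(L = gam_l, M = gam_m, S = gam_s),
      basis = basis,
      alpha = alpha,
      edf = c(
        L = edf_at(gam_l, "L", pmax(7 * cvg$S^2 / 4, 1e-6)),
        M = edf_at(gam_m, "M", pmax((x / cvg$M)^(2 * cvg$L) / cvg$S^2, 0.1 / cvg$S^2)),
        S = edf_at(gam_s, "S", rep(2, length(x)))
      ),
      loglik = sum(cvg$L * log(x / cvg$M) - log(cvg$S) - z_fin^2 / 2),
      penalized_loglik = f_prev,
      loglik_trace = trace,
      converged = converged,
      iterations = iter,
      n_obs = length(x)
    ),
    class = "lms_fit"
  )
}

#' @export
print.lms_fit <- function(x, ...) {
  cat(sprintf(
    "LMS fit%s: n = %d, %d iterations, %sconverged\n",
    if (!is.null(x$sex)) paste0(" (", x$sex, ")") else "",
    x$n_obs, x$iterations, if (x$converged) "" else "NOT "
  ))
  cat(sprintf(
    "  EDF: L %.2f, M %.2f, S %.2f; log-likelihood %.2f\n",
    x$edf["L"], x$edf["M"], x$edf["S"], x$loglik
  ))
  invisible(x)
}

#' @rdname tidy.ri_fit
#' @export
tidy.lms_fit <- function(x, ...) {
  tibble::tibble(age = x$age_grid, L = x$L, M = x$M, S = x$S)
}

#' @rdname tidy.ri_fit
#' @export
glance.lms_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, loglik = x$loglik,
    penalized_loglik = x$penalized_loglik,
    edf_L = x$edf[["L"]], edf_M = x$edf[["M"]], edf_S = x$edf[["S"]],
    iterations = x$iterations, converged = x$converged
  )
}

# evaluate the fitted curves at arbitrary ages
predict_lms <- function(fit, age) {
  Bg <- bspline_eval(fit$basis, age)
  tibble::tibble(
    age = age,
    L = drop(Bg %*% fit$coefficients$L),
    M = exp(drop(Bg %*% fit$coefficients$M)),
    S = exp(drop(Bg %*% fit$coefficients$S))
  )
}

#' Centile table from a fitted LMS model
#'
#' Evaluates `value_from_sds(qnorm(p/100), L(t), M(t), S(t))` for each
#' requested centile over the ages. The 50th centile equals the fitted
#' median curve exactly.
#'
#' @param fit An `lms_fit`.
#' @param centiles Percent values in (0, 100), e.g. `c(3, 50, 97)`.
#' @param ages Evaluation ages (defaults to the fit's grid).
#' @return Tibble: `age`, then one `P<centile>` column per centile.
#' @export
centile_table <- function(fit, centiles = c(3, 10, 25, 50, 75, 90, 97),
                          ages = fit$age_grid) {
  if (any(centiles <= 0 | centiles >= 100)) {
    stop("centiles must lie strictly between 0 and 100", call. = FALSE)
  }
  cv <- predict_lms(fit, ages)
  out <- tibble::tibble(age = ages)
  for (p in centiles) {
    out[[sprintf("P%g", p)]] <-
      value_from_sds(stats::qnorm(p / 100), cv$L, cv$M, cv$S)
  }
  out
}

#' Export a fitted LMS model as a reference table
#'
#' @param fit An `lms_fit` (its `sex` label must be set).
#' @param measure Measure name for the reference rows.
#' @return An [lms_reference()] usable anywhere a reference table is.
#' @export
as_lms_reference <- function(fit, measure = "height-for-age") {
  if (is.null(fit$sex)) stop("fit has no sex label", call. = FALSE)
  lms_reference(tibble::tibble(
    measure = measure, sex = fit$sex, age = fit$age_grid,
    L = fit$L, M = fit$M, S = fit$S
  ))
}

#' Select one random observation per child
#'
#' Reference construction conventionally uses a single randomly selected
#' visit per child to avoid over-representing frequently measured children.
#' Uses the current RNG state (set a seed for reproducibility); the selected
#' row indices are recorded in `attr(, "selected")`.
#'
#' @param data Data frame with a `child_id` column.
#' @return The sampled subset, one row per child.
#' @export
sample_one_per_child <- function(data) {
  idx <- vapply(
    split(seq_len(nrow(data)), data$child_id),
    function(i) if (length(i) == 1) i else sample(i, 1),
    integer(1)
  )
  idx <- sort(unname(idx))
  out <- data[idx, ]
  attr(out, "selected") <- idx
  out
}
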