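# Core LMS (Box-Cox) transforms between measurements, z-scores and centiles.

#' Convert a measurement to a standard deviation score (SDS)
#'
#' Applies Cole's LMS transform. For Box-Cox power `L != 0`,
#' `z = ((x / M)^L - 1) / (L * S)`; for `L == 0`, `z = log(x / M) / S`.
#' `M` is the reference median at the child's age and sex and `S` the
#' coefficient of variation, so the returned value expresses `x` in
#' age- and sex-specific standard deviations from the median.
#'
#' @param x Measurement (same units as `M`, e.g. cm or kg/m^2). Must be > 0.
#' @param L Box-Cox power (dimensionless).
#' @param M Reference median (> 0).
#' @param S Reference coefficient of variation (> 0).
#' @return Numeric vector of z-scores. `sds()` and [value_from_sds()] are
#'   exact inverses of each other.
#' @examples
#' sds(105, L = 1, M = 100, S = 0.05) # 1
#' sds(100 * exp(0.05), L = 0, M = 100, S = 0.05) # 1
#' @export
sds <- function(x, L, M, S) {
  check_lms(L, M, S)
  if (any(!is.finite(x) | x <= 0)) {
    stop("`x` must be positive and finite for the Box-Cox transform", call. = FALSE)
  }
  lms_z(x, L, M, S)
}

# unchecked vectorised core; tolerates x = 0 when L > 0 (used for velocities)
lms_z <- function(x, L, M, S) {
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n)
  L <- rep_len(L, n)
  M <- rep_len(M, n)
  S <- rep_len(S, n)
  out <- numeric(n)
  sm <- abs(L) < 1e-12
  out[sm] <- log(x[sm] / M[sm]) / S[sm]
  out[!sm] <- ((x[!sm] / M[!sm])^L[!sm] - 1) / (L[!sm] * S[!sm])
  out
}

#' Convert an SDS back to a measurement
#'
#' Inverse LMS transform: `x = M * (1 + L * S * z)^(1/L)` for `L != 0`, and
#' `x = M * exp(S * z)` for `L == 0`.
#'
#' @param z Standard deviation score.
#' @inheritParams sds
#' @return Measurement on the original scale. Errors when
#'   `1 + L * S * z <= 0` (the requested centile lies outside the Box-Cox
#'   support for these parameters).
#' @examples
#' value_from_sds(2, L = 1, M = 100, S = 0.05) # 110
#' @export
value_from_sds <- function(z, L, M, S) {
  check_lms(L, M, S)
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n)
  L <- rep_len(L, n)
  M <- rep_len(M, n)
  S <- rep_len(S, n)
  base <- 1 + L * S * z
  sm <- abs(L) < 1e-12
  if (any(!sm & base <= 0, na.rm = TRUE)) {
    stop("SDS outside the Box-Cox support: 1 + L*S*z must be > 0", call. = FALSE)
  }
  out <- numeric(n)
  out[sm] <- M[sm] * exp(S[sm] * z[sm])
  out[!sm] <- M[!sm] * base[!sm]^(1 / L[!sm])
  out
}

#' Centile corresponding to an SDS
#'
#' @param z Standard deviation score.
#' @return `pnorm(z) * 100`, the percent of the reference population expected
#'   below the measurement; strictly increasing in `z`.
#' @examples
#' centile(0) # 50
#' centile(1.88) # ~97 (the conventional P97 cutoff)
#' @export
centile <- function(z) {
  stats::pnorm(z) * 100
}

check_lms <- function(L, M, S) {
  if (any(!is.finite(L)) || any(!is.finite(M)) || any(!is.finite(S)) ||
    any(M <= 0) || any(S <= 0)) {
    stop("invalid LMS parameters: need finite L, M > 0, S > 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-observation Box-Cox normal log-likelihood
#'
#' Log density (up to a constant in the data) of a measurement under the
#' LMS model: `L * log(x/M) - log(S) - z^2 / 2`, with `z` from [sds()].
#' This is the objective summed and penalized by [fit_lms()].
#'
#' @inheritParams sds
#' @return Numeric vector of log-likelihood contributions (additive constant
#'   `-log(x) - log(2*pi)/2` omitted consistently).
#' @export
loglik_boxcox <- function(x, L, M, S) {
  check_lms(L, M, S)
  if (any(!is.finite(x) | x <= 0)) {
    stop("`x` must be positive and finite", call. = FALSE)
  }
  z <- lms_z(x, L, M, S)
  L * log(x / M) - log(S) - z^2 / 2
}
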