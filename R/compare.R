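# Two-group per-age-group contrasts with Holm-Sidak multiplicity correction.

#' Holm-Sidak step-down adjusted p-values
#'
#' Sorts the p-values ascending, applies the Sidak adjustment
#' `1 - (1 - p_(i))^(m - i + 1)` to the i-th smallest of `m`, enforces the
#' step-down running maximum, caps at 1, and returns the values in the
#' original order. Controls the family-wise error rate at the nominal level.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order and length as `p`.
#' @examples
#' holm_sidak(c(0.01, 0.04, 0.03))
#' @export
holm_sidak <- function(p) {
  if (!length(p)) {
    return(numeric(0))
  }
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Per-age-group two-group comparison
#'
#' For each age group with at least `min_n` observations in both groups, the
#' group means are compared with an unpaired t-test (Welch by default);
#' the family of all non-suppressed age groups is then corrected with
#' [holm_sidak()]. Strata with fewer than `min_n` in either group are
#' suppressed: their descriptive statistics are reported, but they carry no
#' p-value and do not enter the correction family. Strata where both groups
#' have zero variance are flagged `degenerate` (p undefined).
#'
#' @param data Tibble holding one row per observation.
#' @param value Name of the numeric outcome column.
#' @param group Name of the grouping column (e.g. `weight_category`).
#' @param group_a,group_b The two group levels to contrast; differences are
#'   `mean_a - mean_b` and percent differences `100 * (mean_a - mean_b) / mean_b`.
#' @param by Name of the stratifying column (default `age_group`). The
#'   caller is responsible for restricting `data` to one outcome and one sex:
#'   the correction family is exactly the strata of one call.
#' @param min_n Minimum per-group sample size (default 6).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param alpha Significance level for the adjusted p-values.
#' @return A `growth_comparison` tibble with one row per stratum:
#'   `age_group`, `n_a`, `n_b`, `mean_a`, `sem_a`, `mean_b`, `sem_b`,
#'   `diff`, `pct_diff`, `p_raw`, `p_adj`, `significant`, `suppressed`,
#'   `degenerate`.
#' @export
compare_groups <- function(data, value, group, group_a, group_b,
                           by = "age_group", min_n = 6,
                           var_equal = FALSE, alpha = 0.05) {
  stopifnot(all(c(value, group, by) %in% names(data)))
  g <- as.character(data[[group]])
  keep <- g %in% c(group_a, group_b) & !is.na(data[[value]])
  d <- tibble::tibble(
    stratum = data[[by]][keep],
    value = data[[value]][keep],
    in_a = g[keep] == group_a
  )
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  res <- d |>
    dplyr::summarise(
      n_a = sum(.data$in_a),
      n_b = sum(!.data$in_a),
      mean_a = mean(.data$value[.data$in_a]),
      sem_a = sem(.data$value[.data$in_a]),
      mean_b = mean(.data$value[!.data$in_a]),
      sem_b = sem(.data$value[!.data$in_a]),
      var_a = stats::var(.data$value[.data$in_a]),
      var_b = stats::var(.data$value[!.data$in_a]),
      .by = "stratum"
    ) |>
    dplyr::arrange(.data$stratum)
  res$diff <- res$mean_a - res$mean_b
  res$pct_diff <- 100 * res$diff / res$mean_b
  res$suppressed <- res$n_a < min_n | res$n_b < min_n
  res$degenerate <- !res$suppressed &
    res$var_a %in% 0 & res$var_b %in% 0
  res$p_raw <- NA_real_
  testable <- which(!res$suppressed & !res$degenerate)
  for (i in testable) {
    xa <- d$value[d$stratum == res$stratum[i] & d$in_a]
    xb <- d$value[d$stratum == res$stratum[i] & !d$in_a]
    res$p_raw[i] <- stats::t.test(xa, xb, var.equal = var_equal)$p.value
  }
  res$p_adj <- NA_real_
  res$p_adj[testable] <- holm_sidak(res$p_raw[testable])
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res$var_a <- res$var_b <- NULL
  names(res)[names(res) == "stratum"] <- by
  class(res) <- c("growth_comparison", class(res))
  res
}

#' Largest between-group difference across age groups
#'
#' Finds the age group with the extreme difference in a comparison table,
#' over the non-suppressed strata within an optional age window. Ties are
#' broken toward the youngest group.
#'
#' @param result A [compare_groups()] table.
#' @param metric `"absolute"` (the `diff` column; alias `"sds"` when the
#'   outcome already is an SDS) or `"percent"` (`pct_diff`).
#' @param window Optional `c(lo, hi)` inclusive range of age-group codes.
#' @param direction `"max"` for the largest, `"min"` for the most negative
#'   difference (e.g. the deepest percent reduction).
#' @return One-row tibble: `age_group`, `value`.
#' @export
max_group_difference <- function(result, metric = c("absolute", "sds", "percent"),
                                 window = NULL, direction = c("max", "min")) {
  metric <- match.arg(metric)
  direction <- match.arg(direction)
  v <- if (metric == "percent") result$pct_diff else result$diff
  keep <- !result$suppressed & !is.na(v)
  if (!is.null(window)) {
    keep <- keep & result$age_group >= window[1] & result$age_group <= window[2]
  }
  if (!any(keep)) stop("no non-suppressed strata in the window", call. = FALSE)
  v <- ifelse(keep, v, NA_real_)
  target <- if (direction == "max") max(v, na.rm = TRUE) else min(v, na.rm = TRUE)
  at <- which(v == target)
  at <- at[which.min(result$age_group[at])]
  tibble::tibble(age_group = result$age_group[at], value = v[at])
}
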