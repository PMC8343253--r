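# ggplot2 helpers for the package's result types.

#' Plot a per-age-group comparison
#'
#' Mean +/- SEM of both groups by age group, with asterisks over strata whose
#' Holm-Sidak-adjusted p is below the significance level. Facets by sex when
#' a `sex` column is present.
#'
#' @param object A `growth_comparison` tibble (from [compare_groups()] or
#'   [analyte_contrast()]).
#' @param labels Names used in the legend for groups a and b.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growth_comparison <- function(object, labels = c("group a", "group b"),
                                       ...) {
  d <- object[!object$suppressed, ]
  long <- dplyr::bind_rows(
    tibble::tibble(
      sex = if ("sex" %in% names(d)) d$sex else "all",
      age_group = d$age_group, group = labels[1],
      mean = d$mean_a, sem = d$sem_a
    ),
    tibble::tibble(
      sex = if ("sex" %in% names(d)) d$sex else "all",
      age_group = d$age_group, group = labels[2],
      mean = d$mean_b, sem = d$sem_b
    )
  )
  stars <- d[d$significant & !is.na(d$significant), ]
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$age_group, y = .data$mean,
    colour = .data$group, shape = .data$group
  )) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$sem,
      ymax = .data$mean + .data$sem
    ), position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::labs(x = "age group (years)", y = NULL, colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
  if (nrow(stars)) {
    ymax <- max(long$mean + long$sem, na.rm = TRUE)
    p <- p + ggplot2::geom_text(
      data = tibble::tibble(
        sex = if ("sex" %in% names(stars)) stars$sex else "all",
        age_group = stars$age_group, y = ymax * 1.05
      ),
      ggplot2::aes(x = .data$age_group, y = .data$y, label = "*"),
      inherit.aes = FALSE, size = 5
    )
  }
  if ("sex" %in% names(d)) p <- p + ggplot2::facet_wrap(~sex)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot cross-lagged effect estimates by age
#'
#' Effect of BMI SDS at age t on height SDS at t + 1 year, with standard
#' errors and significance asterisks.
#'
#' @param result Output of [cross_lag_effect()] (optionally with a `sex`
#'   column for faceting).
#' @return A ggplot object.
#' @export
plot_cross_lag <- function(result) {
  p <- ggplot2::ggplot(result, ggplot2::aes(x = .data$age_group, y = .data$beta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$beta - .data$se, ymax = .data$beta + .data$se
    )) +
    ggplot2::geom_text(
      data = result[result$significant, ],
      ggplot2::aes(y = .data$beta + .data$se + 0.01, label = "*"), size = 5
    ) +
    ggplot2::labs(
      x = "age group at t (years)",
      y = "height SDS at t+1 per BMI SDS at t"
    ) +
    ggplot2::theme_minimal()
  if ("sex" %in% names(result)) p <- p + ggplot2::facet_wrap(~sex)
  p
}

#' Plot fitted centile curves
#'
#' @param fit An `lms_fit`.
#' @param centiles Centiles to draw.
#' @param reference Optional [lms_reference()] whose median is overlaid for
#'   comparison (dashed).
#' @param measure,sex Reference lookup for the overlay.
#' @return A ggplot object.
#' @export
plot_centiles <- function(fit, centiles = c(3, 50, 97), reference = NULL,
                          measure = "height-for-age", sex = fit$sex) {
  tab <- centile_table(fit, centiles) |>
    tidyr::pivot_longer(-"age", names_to = "centile", values_to = "value")
  p <- ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$age, y = .data$value, group = .data$centile
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "age (years)", y = "value", title = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    ref <- reference[reference$measure == measure & reference$sex == sex, ]
    p <- p + ggplot2::geom_line(
      data = ref, ggplot2::aes(x = .data$age, y = .data$M),
      inherit.aes = FALSE, linetype = 2, colour = "grey50"
    )
  }
  p
}
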