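#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_errorbar geom_vline labs facet_grid position_dodge
#'   scale_x_log10 scale_y_log10 theme_minimal
#' @export
ggplot2::autoplot

#' Log-log fluctuation plot of a DFA fit
#'
#' @param object A `sway_dfa` object.
#' @param ... Unused.
#' @return A ggplot: `F(n)` against box size on log axes with the fitted
#'   power law.
#' @export
autoplot.sway_dfa <- function(object, ...) {
  fl <- object$fluctuations
  fit <- lm(log(fn) ~ log(n), data = fl)
  fl$fitted <- exp(predict(fit))
  ggplot(fl, aes(x = .data$n, y = .data$fn)) +
    geom_line(aes(y = .data$fitted), colour = "grey50", linetype = 2) +
    geom_point() +
    scale_x_log10() + scale_y_log10() +
    labs(x = "box size n (samples)", y = "F(n)",
         title = sprintf("DFA scaling, alpha = %.3f", object$alpha)) +
    theme_minimal()
}

#' Divergence-curve plot of a Rosenstein Lyapunov fit
#'
#' @param object A `sway_lye` object.
#' @param ... Unused.
#' @return A ggplot of mean log2 neighbour distance per step with the fitted
#'   slope over the fit window.
#' @export
autoplot.sway_lye <- function(object, ...) {
  curve <- object$curve
  in_fit <- curve |> filter(.data$step >= object$fit_range[1],
                            .data$step <= object$fit_range[2],
                            is.finite(.data$log2_dist))
  fit <- lm(log2_dist ~ step, data = in_fit)
  in_fit$fitted <- predict(fit)
  ggplot(curve, aes(x = .data$step, y = .data$log2_dist)) +
    geom_point(size = 0.8, alpha = 0.6) +
    geom_line(data = in_fit, aes(y = .data$fitted), colour = "firebrick") +
    labs(x = "divergence step (samples)", y = "mean log2 distance",
         title = sprintf("Rosenstein divergence, LyE = %.3f bits/s", object$lye)) +
    theme_minimal()
}

#' Group x condition summary plot of a study table
#'
#' Anti-logged cell means with 95% normal-theory confidence intervals after
#' the `ln(x+1)` transform, visits pooled — the standard way these sway
#' measures are displayed.
#'
#' @param table Long study table (see [measure_cohort()]).
#' @return A ggplot faceted by measure and axis.
#' @export
plot_study_summary <- function(table) {
  summ <- table |>
    filter(is.finite(.data$value)) |>
    group_by(.data$subject, .data$group, .data$condition, .data$axis, .data$measure) |>
    summarise(value = mean(log1_transform(.data$value)), .groups = "drop") |>
    group_by(.data$group, .data$condition, .data$axis, .data$measure) |>
    summarise(
      m = mean(.data$value), se = sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    mutate(
      mean = log1_inverse(.data$m),
      lo = log1_inverse(.data$m - 1.96 * .data$se),
      hi = log1_inverse(.data$m + 1.96 * .data$se)
    )
  ggplot(summ, aes(x = .data$condition, y = .data$mean, fill = .data$group)) +
    geom_col(position = position_dodge(0.9), width = 0.8) +
    geom_errorbar(aes(ymin = .data$lo, ymax = .data$hi),
                  position = position_dodge(0.9), width = 0.2) +
    facet_grid(measure ~ axis, scales = "free_y") +
    labs(x = NULL, y = "anti-logged mean (95% CI)", fill = NULL) +
    theme_minimal()
}
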