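#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a mixed-ANOVA fit
#'
#' @param x A `sway_anova` object.
#' @param ... Unused.
#' @return Tibble with one row per effect: `effect`, `df1`, `df2`, `F`, `p`,
#'   `peta2` (partial eta squared) and Cohen's `f`.
#' @export
tidy.sway_anova <- function(x, ...) {
  x$table |> select("effect", "df1", "df2", "F", "p", "peta2", "f")
}

#' @rdname tidy.sway_anova
#' @return `glance()`: one-row tibble with the numbers of subjects, groups
#'   and within-subject cells.
#' @export
glance.sway_anova <- function(x, ...) {
  tibble(
    n_subjects = dplyr::n_distinct(x$data$subject),
    n_groups = dplyr::n_distinct(x$data$group),
    n_cells = dplyr::n_distinct(interaction(x$data$condition, x$data$visit))
  )
}

#' Tidy a DFA fit
#'
#' @param x A `sway_dfa` object.
#' @param ... Unused.
#' @return `tidy()`: the per-scale fluctuation table (`n`, `fn`);
#'   `glance()`: one row with `alpha` and the number of scales.
#' @export
tidy.sway_dfa <- function(x, ...) x$fluctuations

#' @rdname tidy.sway_dfa
#' @export
glance.sway_dfa <- function(x, ...) {
  tibble(alpha = x$alpha, n_scales = nrow(x$fluctuations),
         n_min = min(x$fluctuations$n), n_max = max(x$fluctuations$n))
}

#' Tidy a Rosenstein divergence fit
#'
#' @param x A `sway_lye` object.
#' @param ... Unused.
#' @return `tidy()`: the divergence curve (`step`, `log2_dist`, `n_pairs`);
#'   `glance()`: one row with the exponent and fit metadata.
#' @export
tidy.sway_lye <- function(x, ...) x$curve

#' @rdname tidy.sway_lye
#' @export
glance.sway_lye <- function(x, ...) {
  tibble(lye = x$lye, slope_per_step = x$slope_per_step, fs = x$fs,
         m = x$m, tau = x$tau, fit_lo = x$fit_range[1], fit_hi = x$fit_range[2])
}
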