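#' Shifted-log transform used before inference
#'
#' `ln(x + 1)` elementwise, with the inverse `exp(y) - 1` for reporting
#' descriptives on the original scale.
#'
#' @param x Values greater than -1.
#' @return Transformed values.
#' @export
log1_transform <- function(x) {
  if (any(x[is.finite(x)] <= -1)) abort("log1_transform requires values > -1")
  log1p(x)
}

#' @rdname log1_transform
#' @export
log1_inverse <- function(x) expm1(x)

#' Three-way mixed ANOVA for the 2 x 2 x 2 sway design
#'
#' Fits the classical univariate mixed-design decomposition with `group`
#' (between subjects) and `condition`, `visit` (within subjects): the
#' between effect is tested against the subjects-within-groups mean square
#' and each within-subject effect against its own interaction with subjects
#' within groups. With two levels per factor no sphericity correction is
#' needed. Values are analysed as supplied; apply [log1_transform()] first to
#' match the reporting convention.
#'
#' @param data Long data frame with columns `subject`, `group`, `condition`,
#'   `visit`, `value` — one row per subject x condition x visit cell.
#' @return A `sway_anova` object; `tidy()` yields one row per effect with
#'   `F`, `df1`, `df2`, `p`, partial eta squared and Cohen's `f`.
#' @export
mixed_anova_2x2x2 <- function(data) {
  data <- as_tibble(data)
  need <- c("subject", "group", "condition", "visit", "value")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(data$value))) abort("non-finite values in the design")
  cells <- data |> count(.data$subject, .data$condition, .data$visit)
  if (any(cells$n != 1)) abort("more than one row per subject x condition x visit cell")
  grid <- data |> count(.data$subject) |> pull(n)
  n_cells <- length(unique(data$condition)) * length(unique(data$visit))
  if (any(grid != n_cells)) {
    bad <- data |> count(.data$subject) |> filter(n != n_cells) |> pull(.data$subject)
    abort(paste0("incomplete within-subject cells for subject(s): ",
                 paste(bad, collapse = ", ")))
  }
  per_group <- data |> distinct(.data$subject, .data$group) |> count(.data$group)
  if (nrow(per_group) != 2 || any(per_group$n < 2)) {
    abort("need two groups with at least 2 subjects each")
  }
  d <- data |> mutate(
    subject = factor(.data$subject), group = factor(.data$group),
    condition = factor(.data$condition), visit = factor(.data$visit)
  )
  fit <- aov(value ~ group * condition * visit + Error(subject / (condition * visit)),
             data = d)
  strata <- summary(fit)
  rows <- purrr::imap(strata, function(s, nm) {
    tab <- s[[1]]
    terms <- trimws(rownames(tab))
    res_i <- which(terms == "Residuals")
    eff_i <- setdiff(seq_along(terms), res_i)
    if (!length(eff_i)) return(NULL)
    tibble(
      effect = gsub(":", " x ", terms[eff_i]),
      df1 = tab$Df[eff_i], df2 = tab$Df[res_i],
      ss = tab$`Sum Sq`[eff_i], ss_error = tab$`Sum Sq`[res_i],
      F = tab$`F value`[eff_i], p = tab$`Pr(>F)`[eff_i]
    )
  }) |> list_rbind()
  rows <- rows |> mutate(
    peta2 = .data$ss / (.data$ss + .data$ss_error),
    f = cohens_f_from_eta(.data$peta2)
  )
  order_ref <- c("group", "condition", "visit", "group x condition",
                 "group x visit", "condition x visit", "group x condition x visit")
  rows <- rows |> arrange(match(.data$effect, order_ref))
  structure(list(table = rows, data = d), class = "sway_anova")
}

#' @export
print.sway_anova <- function(x, ...) {
  cat("<sway_anova> three-way mixed ANOVA\n")
  print(as.data.frame(x$table[c("effect", "df1", "df2", "F", "p", "f")]),
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' Cohen's f effect size
#'
#' `f = sqrt(eta2 / (1 - eta2))`; for a two-group t statistic,
#' `eta2 = t^2 / (t^2 + df)`. Conventional bands: small > 0.10,
#' medium > 0.25, large > 0.40.
#'
#' @param eta2 Partial eta squared in `[0, 1)`.
#' @return Cohen's f.
#' @export
cohens_f_from_eta <- function(eta2) {
  if (any(eta2 < 0 | eta2 >= 1)) abort("eta2 must lie in [0, 1)")
  sqrt(eta2 / (1 - eta2))
}

#' @rdname cohens_f_from_eta
#' @param t,df t statistic and its degrees of freedom.
#' @export
cohens_f_from_t <- function(t, df) {
  cohens_f_from_eta(t^2 / (t^2 + df))
}

#' Independent two-sample t test from summary statistics
#'
#' Pooled-variance two-sided test (identical to the unpooled statistic when
#' group sizes are equal), as used for baseline group comparisons.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @return One-row tibble with `t`, `df`, `p`, `mean_diff` and Cohen's `f`.
#' @export
independent_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) abort("need n >= 2 per group")
  if (sd1 < 0 || sd2 < 0) abort("standard deviations must be >= 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) {
    if (mean1 == mean2) 0 else Inf * sign(mean1 - mean2)
  } else {
    (mean1 - mean2) / se
  }
  tibble(t = t, df = df, p = 2 * pt(-abs(t), df), mean_diff = mean1 - mean2,
         f = cohens_f_from_t(t, df))
}

#' Benjamini-Hochberg step-up decisions within declared families
#'
#' Adjusts p values within each family by the false-discovery-rate step-up
#' rule and reports which comparisons survive at level `alpha`.
#'
#' @param comparisons Data frame with at least columns `family`, `p`
#'   (other columns are carried through).
#' @param alpha FDR level.
#' @return The input tibble plus `p_adj`, `rank` and `significant`.
#' @export
posthoc_pairwise_bh <- function(comparisons, alpha = 0.05) {
  comparisons <- as_tibble(comparisons)
  if (!all(c("family", "p") %in% names(comparisons))) {
    abort("need columns 'family' and 'p'")
  }
  if (any(comparisons$p < 0 | comparisons$p > 1, na.rm = TRUE)) {
    abort("p values must lie in [0, 1]")
  }
  comparisons |>
    group_by(.data$family) |>
    mutate(
      rank = rank(.data$p, ties.method = "first"),
      p_adj = p.adjust(.data$p, method = "BH"),
      significant = .data$p_adj <= alpha
    ) |>
    ungroup()
}

#' One-way random single-measure intraclass correlation, ICC(1,1)
#'
#' Test-retest agreement from a one-way random-effects decomposition over
#' subjects: with two visits, `ICC = (MSB - MSW) / (MSB + MSW)` where MSB and
#' MSW are the between- and within-subject mean squares. Bands follow the
#' conventional thresholds: poor <= 0.40 < fair <= 0.60 < good <= 0.75 <
#' excellent.
#'
#' @param visit1,visit2 Paired measurements, length >= 3.
#' @return One-row tibble with `icc`, `msb`, `msw`, `band`.
#' @export
icc_1_1 <- function(visit1, visit2) {
  if (length(visit1) != length(visit2)) abort("visits must be paired")
  n <- length(visit1)
  if (n < 3) abort("need at least 3 subjects")
  k <- 2
  ymat <- cbind(visit1, visit2)
  subj_means <- rowMeans(ymat)
  grand <- mean(ymat)
  msb <- k * sum((subj_means - grand)^2) / (n - 1)
  msw <- sum((ymat - subj_means)^2) / (n * (k - 1))
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  tibble(icc = icc, msb = msb, msw = msw, band = icc_band(icc))
}

icc_band <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.40, 0.60, 0.75, Inf),
      labels = c("poor", "fair", "good", "excellent"), right = TRUE) |>
    as.character()
}

#' Reliability gate on a grid of ICC values
#'
#' A measure x axis combination is excluded from inferential testing when any
#' of its group x condition cells has `ICC <= threshold` (the "poor" band);
#' its descriptives remain reportable.
#'
#' @param icc_rows Data frame with columns `measure`, `axis`, `group`,
#'   `condition`, `icc`.
#' @param threshold Poor-reliability bound.
#' @return Tibble of excluded `measure`, `axis` pairs with the offending cell.
#' @export
reliability_gate <- function(icc_rows, threshold = 0.40) {
  icc_rows <- as_tibble(icc_rows)
  need <- c("measure", "axis", "group", "condition", "icc")
  if (!all(need %in% names(icc_rows))) {
    abort(paste0("need columns: ", paste(need, collapse = ", ")))
  }
  icc_rows |>
    group_by(.data$measure, .data$axis) |>
    summarise(
      min_icc = min(.data$icc),
      worst_cell = paste(.data$group[which.min(.data$icc)],
                         .data$condition[which.min(.data$icc)]),
      .groups = "drop"
    ) |>
    filter(.data$min_icc <= threshold)
}

#' Bias-corrected and accelerated bootstrap CI for a mean difference
#'
#' Resamples each group independently, corrects the percentile interval for
#' median bias (`z0`, from the fraction of bootstrap statistics below the
#' observed difference) and skewness (acceleration `a`, from the jackknife
#' influence values of both samples).
#'
#' @param sample1,sample2 Numeric samples (difference is mean1 - mean2).
#' @param B Bootstrap resamples.
#' @param alpha Two-sided miss probability (0.05 gives a 95% interval).
#' @param seed Integer seed for the resampling stream.
#' @return Tibble with `estimate`, `lo`, `hi`, `z0`, `a`.
#' @export
bca_ci <- function(sample1, sample2, B = 10000, alpha = 0.05, seed = 1) {
  n1 <- length(sample1); n2 <- length(sample2)
  if (n1 < 2 || n2 < 2) abort("need at least 2 observations per sample")
  obs <- mean(sample1) - mean(sample2)
  boot <- with_stream(seed, "bca", expr = {
    i1 <- matrix(sample.int(n1, n1 * B, replace = TRUE), nrow = B)
    i2 <- matrix(sample.int(n2, n2 * B, replace = TRUE), nrow = B)
    rowMeans(matrix(sample1[i1], nrow = B)) - rowMeans(matrix(sample2[i2], nrow = B))
  })
  if (all(boot == obs)) {
    return(tibble(estimate = obs, lo = obs, hi = obs, z0 = 0, a = 0))
  }
  z0 <- qnorm(mean(boot < obs) + 0.5 * mean(boot == obs))
  # jackknife influence of each observation on the mean difference
  jack <- c(
    vapply(seq_len(n1), function(i) mean(sample1[-i]) - mean(sample2), numeric(1)),
    vapply(seq_len(n2), function(i) mean(sample1) - mean(sample2[-i]), numeric(1))
  )
  u <- mean(jack) - jack
  a <- sum(u^3) / (6 * sum(u^2)^1.5)
  if (!is.finite(a)) a <- 0
  zq <- qnorm(c(alpha / 2, 1 - alpha / 2))
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  ci <- unname(quantile(boot, probs = adj, type = 6))
  tibble(estimate = obs, lo = ci[1], hi = ci[2], z0 = z0, a = a)
}

#' Weight-status classification from a BMI percentile
#'
#' @param bmi_percentile Percentile in `[0, 100]`.
#' @return Character class: `underweight` (< 5), `normal` (5 <= p < 85),
#'   `overweight` (85 <= p < 95) or `obese` (>= 95).
#' @export
classify_weight <- function(bmi_percentile) {
  if (any(bmi_percentile < 0 | bmi_percentile > 100)) {
    abort("BMI percentile must lie in [0, 100]")
  }
  dplyr::case_when(
    bmi_percentile >= 95 ~ "obese",
    bmi_percentile >= 85 ~ "overweight",
    bmi_percentile >= 5 ~ "normal",
    TRUE ~ "underweight"
  )
}
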