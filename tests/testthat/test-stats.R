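test_that("shifted-log transform round-trips and hits closed forms", {
  expect_equal(log1_transform(0), 0)
  expect_equal(log1_transform(exp(1) - 1), 1)
  set.seed(1)
  x <- runif(50, -0.5, 10)
  expect_equal(log1_inverse(log1_transform(x)), x, tolerance = 1e-12)
  expect_error(log1_transform(-1.5), "> -1")
})

test_that("mixed ANOVA F values match the balanced projection oracle", {
  for (seed in 1:3) {
    d <- make_design(8, seed = seed, cond_effect = 0.4, group_effect = 0.3)
    got <- tidy(mixed_anova_2x2x2(d))
    ref <- anova_brute(d)
    expect_equal(got$F, ref$F[match(got$effect, ref$effect)], tolerance = 1e-8)
    expect_equal(got$df1, rep(1, 7))
    expect_equal(got$df2, rep(2 * (8 - 1), 7))
  }
})

test_that("mixed ANOVA has a calibrated type-I error under the null", {
  rej <- replicate(1000, {
    d <- make_design(6, seed = sample.int(1e8, 1))
    tidy(mixed_anova_2x2x2(d))$p[1] < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("the between-group F collapses to the squared two-sample t", {
  d <- make_design(10, seed = 4, group_effect = 0.5)
  fit <- tidy(mixed_anova_2x2x2(d))
  means <- d |> dplyr::group_by(subject, group) |>
    dplyr::summarise(value = mean(value), .groups = "drop")
  tt <- t.test(value ~ group, data = means, var.equal = TRUE)
  expect_equal(fit$F[fit$effect == "group"], unname(tt$statistic)^2, tolerance = 1e-8)
})

test_that("incomplete designs are rejected naming the offender", {
  d <- make_design(4, seed = 5)
  expect_error(mixed_anova_2x2x2(d[-1, ]), "s01")
  d2 <- d
  d2$value[3] <- NA
  expect_error(mixed_anova_2x2x2(d2), "non-finite")
})

test_that("effect sizes reproduce the published baseline comparisons", {
  # group summary rows as printed: body mass then BMI percentile
  mass <- independent_t(64.0, 10.8, 19, 46.4, 9.6, 19)
  expect_equal(mass$t, 5.32, tolerance = 0.05)
  expect_lt(mass$p, 0.001)
  pct <- independent_t(93.4, 3.7, 19, 45.1, 22.5, 19)
  expect_equal(pct$t, 9.22, tolerance = 0.05)
  expect_equal(cohens_f_from_t(5.32, 36), 0.89, tolerance = 0.02)
  expect_equal(cohens_f_from_t(9.22, 36), 1.54, tolerance = 0.02)
  expect_equal(cohens_f_from_t(0, 30), 0)
  expect_equal(cohens_f_from_eta(0.5), 1)
  ident <- independent_t(5, 1, 10, 5, 1, 10)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
})

test_that("BH decisions match the step-up definition and are monotone", {
  set.seed(6)
  p <- runif(10)
  got <- posthoc_pairwise_bh(tibble::tibble(family = "f", p = p), alpha = 0.05)
  expect_equal(got$significant, bh_brute(p, 0.05))

  # equal p values: all or nothing
  peq <- rep(0.03, 4)
  geq <- posthoc_pairwise_bh(tibble::tibble(family = "f", p = peq), alpha = 0.05)
  expect_true(all(geq$significant))
  geq2 <- posthoc_pairwise_bh(tibble::tibble(family = "f", p = rep(0.06, 4)), 0.05)
  expect_false(any(geq2$significant))

  # single comparison reduces to the unadjusted test
  one <- posthoc_pairwise_bh(tibble::tibble(family = "f", p = 0.04), 0.05)
  expect_equal(one$p_adj, 0.04)

  # lowering one p never de-selects another hypothesis
  p2 <- p; p2[which.max(p)] <- 0.001
  got2 <- posthoc_pairwise_bh(tibble::tibble(family = "f", p = p2), alpha = 0.05)
  unchanged <- p2 == p
  expect_true(all(got2$significant[unchanged] >= got$significant[unchanged]))
})

test_that("ICC(1,1) matches its mean-square definition and bands", {
  set.seed(7)
  v1 <- rnorm(10)
  same <- icc_1_1(v1, v1)
  expect_equal(same$icc, 1)
  expect_equal(same$band, "excellent")

  iccs <- replicate(100, {
    a <- rnorm(12); b <- rnorm(12)
    icc_1_1(a, b)$icc
  })
  expect_equal(mean(iccs), 0, tolerance = 0.1)

  # 6-subject worked table against one-way ANOVA mean squares
  y1 <- c(9.1, 8.2, 7.9, 10.4, 9.9, 8.8)
  y2 <- c(9.4, 8.0, 8.3, 10.1, 10.3, 8.6)
  got <- icc_1_1(y1, y2)
  long <- data.frame(subject = factor(rep(1:6, 2)), y = c(y1, y2))
  ms <- anova(lm(y ~ subject, data = long))
  msb <- ms$`Mean Sq`[1]; msw <- ms$`Mean Sq`[2]
  expect_equal(got$icc, (msb - msw) / (msb + msw), tolerance = 1e-10)

  # invariance to a common affine transform
  expect_equal(icc_1_1(2 * y1 + 3, 2 * y2 + 3)$icc, got$icc, tolerance = 1e-10)
})

test_that("the reliability gate excludes any measure with a poor cell", {
  grid <- tidyr::expand_grid(measure = c("sen", "alpha_dfa"), axis = c("ML", "AP"),
                             group = c("YO", "YN"), condition = c("firm", "foam"))
  grid$icc <- 0.7
  grid$icc[grid$measure == "alpha_dfa" & grid$axis == "AP" &
             grid$group == "YN" & grid$condition == "foam"] <- 0.20
  out <- reliability_gate(grid, 0.40)
  expect_equal(nrow(out), 1)
  expect_equal(out$measure, "alpha_dfa")
  expect_equal(out$axis, "AP")

  grid$icc[grid$icc == 0.20] <- 0.40  # boundary: poor is ICC <= 0.40
  expect_equal(nrow(reliability_gate(grid, 0.40)), 1)
  grid$icc[grid$icc == 0.40] <- 0.41
  expect_equal(nrow(reliability_gate(grid, 0.40)), 0)
})

test_that("BCa interval collapses for constant samples and reduces to percentile", {
  const <- bca_ci(rep(2, 5), rep(1, 5), B = 200, seed = 8)
  expect_equal(const$lo, 1)
  expect_equal(const$hi, 1)

  set.seed(9)
  s1 <- rnorm(19, 5); s2 <- rnorm(19)
  got <- bca_ci(s1, s2, B = 2000, seed = 10)
  boot <- swaycomplexity:::with_stream(10, "bca", expr = {
    i1 <- matrix(sample.int(19, 19 * 2000, replace = TRUE), nrow = 2000)
    i2 <- matrix(sample.int(19, 19 * 2000, replace = TRUE), nrow = 2000)
    rowMeans(matrix(s1[i1], nrow = 2000)) - rowMeans(matrix(s2[i2], nrow = 2000))
  })
  # forcing z0 = 0 and a = 0 in the BCa quantile formula gives the plain
  # percentile interval on the same bootstrap draws
  plain <- unname(quantile(boot, c(0.025, 0.975), type = 6))
  expect_equal(unname(quantile(boot, pnorm(qnorm(c(0.025, 0.975))), type = 6)), plain)
  expect_true(got$lo <= got$estimate && got$estimate <= got$hi)
  expect_equal(got$lo, plain[1], tolerance = 0.2)
  expect_equal(got$hi, plain[2], tolerance = 0.2)
})

test_that("BCa intervals attain nominal coverage on Gaussian samples", {
  true_diff <- 1
  cover <- replicate(500, {
    s1 <- rnorm(19, true_diff); s2 <- rnorm(19)
    ci <- bca_ci(s1, s2, B = 500, seed = sample.int(1e8, 1))
    ci$lo <= true_diff && true_diff <= ci$hi
  })
  expect_equal(mean(cover), 0.95, tolerance = 0.03)
})

test_that("weight-status thresholds partition the percentile axis", {
  expect_equal(classify_weight(45.1), "normal")
  expect_equal(classify_weight(85), "overweight")
  expect_equal(classify_weight(95), "obese")
  expect_equal(classify_weight(93.4), "overweight")
  expect_equal(classify_weight(3), "underweight")
  grid <- seq(0, 100, by = 0.5)
  cls <- classify_weight(grid)
  expect_true(all(!is.na(cls)))
  expect_equal(sort(unique(cls)),
               sort(c("underweight", "normal", "overweight", "obese")))
  # class boundaries occur exactly at 5, 85, 95
  expect_equal(grid[which(diff(as.integer(factor(cls, levels = c(
    "underweight", "normal", "overweight", "obese")))) != 0) + 1], c(5, 85, 95))
  expect_error(classify_weight(101), "\\[0, 100\\]")
})
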