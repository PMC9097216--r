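test_that("rms matches its closed forms and the elementwise oracle", {
  expect_equal(rms_sway(c(1, -1, 1, -1)), 1000)
  s <- sin(2 * pi * 2 * (0:9999) / 100)
  expect_equal(rms_sway(s, unit_scale = 1), 1 / sqrt(2), tolerance = 1e-3)
  set.seed(1)
  x <- rnorm(100)
  expect_equal(rms_sway(x, 1), sqrt(sum(x^2) / 100))
  expect_error(rms_sway(1), "2 samples")
})

test_that("sample entropy is zero for a perfectly repeatable signal", {
  x <- gen_oracle_signals("periodic_pattern", 500)
  sen <- sample_entropy(x, M = 3, r_frac = 0.2)
  expect_identical(as.numeric(sen), 0)
  expect_equal(attr(sen, "A") / attr(sen, "B"), 1)
})

test_that("sample entropy equals brute-force template counting", {
  toy <- rep(c(1, 2), 5)
  got <- sample_entropy(toy, M = 2, r_frac = 0.5)
  ref <- sampen_brute(toy, 2, 0.5 * sd(toy))
  expect_equal(attr(got, "A"), ref$A)
  expect_equal(attr(got, "B"), ref$B)
  expect_equal(as.numeric(got), ref$sen)

  set.seed(2)
  for (n in c(120, 300, 500)) {
    x <- rnorm(n)
    r <- 0.2 * sd(x)
    got <- sample_entropy(x, M = 2, r = r)
    ref <- sampen_brute(x, 2, r)
    expect_equal(attr(got, "A"), ref$A)
    expect_equal(attr(got, "B"), ref$B)
    expect_equal(as.numeric(got), ref$sen, tolerance = 1e-12)
  }
})

test_that("sample entropy responds to tolerance and template length as theory predicts", {
  set.seed(3)
  x <- runif(5000)
  s_tight <- as.numeric(sample_entropy(x, M = 3, r_frac = 0.07))
  s_loose <- as.numeric(sample_entropy(x, M = 3, r_frac = 0.2))
  expect_gt(s_tight, s_loose)
  # memoryless signal: the conditional match probability does not depend on
  # the template length, so entropy is flat in M up to estimation noise
  s_m2 <- as.numeric(sample_entropy(x, M = 2, r_frac = 0.2))
  s_m3 <- as.numeric(sample_entropy(x, M = 3, r_frac = 0.2))
  expect_equal(s_m3, s_m2, tolerance = 0.05)
  expect_error(sample_entropy(rep(1, 100)), "constant")
})

test_that("degenerate entropy cases warn and return sentinels", {
  set.seed(4)
  x <- rnorm(30)
  expect_warning(out <- sample_entropy(x, M = 2, r = 1e-8), "\\+Inf|no template")
  expect_true(is.infinite(out) || is.na(out))
})

test_that("entropy parameter selection minimises the relative-error metric", {
  set.seed(5)
  records <- lapply(1:6, function(i) gen_colored_noise(400, 1, seed = i))
  # single candidate: returned as-is
  single <- select_sen_params(records, M_grid = 3, r_grid = 0.1)
  expect_equal(single$M, 3)
  expect_equal(single$r_frac, 0.1)
  # a candidate with almost no extending matches loses to a permissive one
  two <- select_sen_params(records, M_grid = 2, r_grid = c(0.001, 0.2))
  expect_equal(two$r_frac, 0.2)
  # exhaustive recomputation oracle
  sel <- select_sen_params(records, M_grid = 2:3, r_grid = c(0.05, 0.1, 0.2))
  metrics <- sapply(seq_len(nrow(sel$grid)), function(k) {
    M <- sel$grid$M[k]; rf <- sel$grid$r_frac[k]
    med <- median(sapply(records, function(x) {
      ref <- sampen_brute(x, M, rf * sd(x))
      if (ref$B == 0 || ref$A == 0) return(Inf)
      cp <- ref$A / ref$B
      sig <- sqrt(cp * (1 - cp) / ref$B)
      max(sig / cp, sig / (cp * abs(log(cp))))
    }))
    med
  })
  expect_equal(sel$grid$metric, metrics, tolerance = 1e-12)
  best <- which(metrics == min(metrics))[1]
  expect_equal(sel$M, sel$grid$M[best])
  expect_equal(sel$r_frac, sel$grid$r_frac[best])
})

test_that("AMI has its first minimum near the quarter period of a sine", {
  s <- gen_oracle_signals("sine", 3000, f = 1, fs = 100)
  tau <- first_minimum(average_mutual_information(s, 60))
  expect_true(abs(tau - 25) <= 2)
})

test_that("AMI of memoryless noise is flat and yields a small delay", {
  set.seed(6)
  x <- rnorm(2000)
  curve <- average_mutual_information(x, 30)
  expect_lt(max(curve$ami), 0.1)
  tau <- suppressWarnings(first_minimum(curve))
  expect_lte(tau, 5)
})

test_that("AMI curve equals a brute-force histogram recount", {
  set.seed(7)
  x <- rnorm(200)
  curve <- average_mutual_information(x, 10)
  bins <- ceiling(200^(1 / 3))
  for (lag in c(1, 4, 9)) {
    expect_equal(curve$ami[lag], ami_brute(x, lag, bins), tolerance = 1e-10)
  }
})

test_that("false neighbours vanish at m = 2 for a sine but not for noise", {
  s <- gen_oracle_signals("sine", 3000, f = 1, fs = 100)
  fr <- false_nearest_neighbors(s, tau = 25, m_max = 3)
  expect_lt(fr$fraction[2], 0.01)
  expect_equal(select_m(fr), 2)

  set.seed(8)
  nz <- rnorm(1200)
  frn <- false_nearest_neighbors(nz, tau = 1, m_max = 5)
  expect_true(all(frn$fraction > 0.01, na.rm = TRUE))
  expect_warning(m <- select_m(frn), "never dropped")
  expect_equal(m, 5)
})

test_that("false-neighbour fractions equal the brute-force search", {
  set.seed(9)
  x <- as.numeric(gen_colored_noise(300, 1.2, seed = 4))
  got <- false_nearest_neighbors(x, tau = 3, m_max = 4)
  ref <- fnn_brute(x, 3, 4)
  expect_equal(got$fraction, ref, tolerance = 1e-12)
})

test_that("delay reconstruction enumerates the expected vectors", {
  x <- 1:10
  emb <- reconstruct(x, m = 2, tau = 3)
  expect_equal(dim(emb), c(7, 2))
  expect_equal(emb[1, ], c(1, 4))
  expect_equal(reconstruct(x, 1, 5), matrix(1:10, ncol = 1))
  set.seed(10)
  y <- rnorm(40)
  expect_equal(reconstruct(y, 3, 2), embed_brute(y, 3, 2))
})

test_that("the logistic map exponent is close to one bit per iteration", {
  x <- gen_oracle_signals("logistic_map", 5000, seed = 11)
  ly <- lyapunov_rosenstein(x, m = 2, tau = 1, fs = 1, fit_range = c(0, 5))
  expect_equal(ly$lye, 1, tolerance = 0.1)
})

test_that("a noiseless periodic orbit shows no divergence", {
  s <- gen_oracle_signals("sine", 4000, f = 2, fs = 100)
  ly <- lyapunov_rosenstein(s, m = 2, tau = 12, fs = 100, fit_range = c(0, 75))
  expect_lt(abs(ly$lye), 0.05)
})

test_that("the divergence curve equals a brute-force all-pairs recomputation", {
  x <- as.numeric(gen_colored_noise(500, 1, seed = 12))
  ly <- lyapunov_rosenstein(x, m = 3, tau = 2, fs = 100, fit_range = c(0, 40))
  ref <- rosenstein_brute(x, 3, 2, theiler = 4, max_steps = 40)
  expect_equal(ly$curve$log2_dist, ref, tolerance = 1e-8)
})

test_that("white noise diverges faster than a same-variance sine", {
  set.seed(13)
  nz <- rnorm(3000)
  s <- sqrt(2) * gen_oracle_signals("sine", 3000, f = 2, fs = 100)
  ly_n <- lyapunov_rosenstein(nz, 4, 5, fs = 100)
  ly_s <- lyapunov_rosenstein(s, 4, 5, fs = 100)
  expect_gt(ly_n$lye, ly_s$lye)
})

test_that("DFA recovers the canonical noise-class exponents", {
  alphas <- sapply(1:20, function(i) {
    set.seed(i)
    dfa(rnorm(5000), 10, 50)$alpha
  })
  expect_equal(mean(alphas), 0.5, tolerance = 0.05)
  browns <- sapply(1:20, function(i) {
    dfa(gen_oracle_signals("brown", 5000, seed = i), 10, 50)$alpha
  })
  expect_equal(mean(browns), 1.5, tolerance = 0.1)
  pinks <- sapply(1:20, function(i) {
    dfa(gen_colored_noise(5000, 1, seed = i), 10, 50)$alpha
  })
  expect_equal(mean(pinks), 1.0, tolerance = 0.1)
})

test_that("DFA is invariant to affine transforms", {
  x <- gen_colored_noise(5000, 1.4, seed = 14)
  a1 <- dfa(x, 10, 50)$alpha
  a2 <- dfa(3.7 * x - 42, 10, 50)$alpha
  expect_equal(a1, a2, tolerance = 1e-10)
  expect_error(dfa(rnorm(100), 10, 50), "4 \\* n_max")
})

test_that("colored-noise exponents map to alpha = (beta + 1) / 2", {
  for (beta in c(0.2, 1.0, 1.8)) {
    alphas <- sapply(1:10, function(i) {
      dfa(gen_colored_noise(5000, beta, seed = 100 * beta + i), 10, 50)$alpha
    })
    expect_equal(mean(alphas), (beta + 1) / 2, tolerance = 0.1)
  }
})

test_that("the frequency band maps to period-equivalent box sizes", {
  sc <- dfa_band_to_scales(c(2, 10), 100)
  expect_equal(sc$n_min, 10)
  expect_equal(sc$n_max, 50)
  clipped <- dfa_band_to_scales(c(1, 50), 100, n = 360)
  expect_equal(clipped$n_min, 4)
  expect_equal(clipped$n_max, 90)
  expect_error(dfa_band_to_scales(c(5, 5), 100), "f_lo < f_hi")
  # an oscillation with an n-sample period peaks at fs/n
  n_box <- 20
  s <- sin(2 * pi * (0:4999) / n_box)
  spec <- Mod(fft(s))[2:2500]
  expect_equal(which.max(spec), 5000 / n_box, tolerance = 1)
})

test_that("complexity profiles are finite, deterministic, and ordered by regularity", {
  cfg <- sway_config()
  rec <- gen_sway_trial(seed = 15)
  pre <- preprocess_trial(rec, cfg)
  p1 <- complexity_profile(pre$signals$ml, "ML", cfg)
  expect_true(all(is.finite(unlist(p1[c("rms", "sen", "lye", "alpha_dfa")]))))
  p2 <- complexity_profile(preprocess_trial(gen_sway_trial(seed = 15), cfg)$signals$ml,
                           "ML", cfg)
  expect_identical(p1, p2)

  regular <- sway_knobs(periodic_weight = 0.7)
  irregular <- sway_knobs(periodic_weight = 0.05)
  sens <- sapply(1:5, function(i) {
    c(
      complexity_profile(preprocess_trial(gen_sway_trial(regular, seed = 20 + i),
                                          cfg)$signals$ml, "ML", cfg)$sen,
      complexity_profile(preprocess_trial(gen_sway_trial(irregular, seed = 20 + i),
                                          cfg)$signals$ml, "ML", cfg)$sen
    )
  })
  expect_lt(mean(sens[1, ]), mean(sens[2, ]))
})
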