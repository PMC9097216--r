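#' Root mean square of a sway acceleration signal
#'
#' @param x Zero-mean acceleration series, m s^-2.
#' @param unit_scale Report multiplier (1000 reports mm s^-2).
#' @return `sqrt(mean(x^2)) * unit_scale`.
#' @export
rms_sway <- function(x, unit_scale = 1000) {
  if (length(x) < 2) abort("need at least 2 samples")
  sqrt(mean(x^2)) * unit_scale
}

#' Sample entropy
#'
#' The negative natural logarithm of the conditional probability that two
#' sub-sequences matching for `M` samples (within a Chebyshev tolerance
#' \code{r = r_frac * sd(x)}) continue to match for `M + 1` samples, with
#' self-matches excluded. Zero for a perfectly repeatable signal; grows as the
#' signal becomes less predictable. When no template pair extends (`A = 0`)
#' the value is `+Inf` with a warning, which downstream statistics treat as
#' missing.
#'
#' @param x Numeric series with positive SD.
#' @param M Template length, samples.
#' @param r_frac Tolerance as a fraction of `sd(x)`.
#' @param r Absolute tolerance; overrides `r_frac` when given.
#' @return Sample entropy (natural-log units), with attributes `A`, `B`
#'   (template-pair counts) and `r` (the tolerance used).
#' @export
sample_entropy <- function(x, M = 3, r_frac = 0.07, r = NULL) {
  if (length(x) <= M + 1) abort("series too short for template length M")
  s <- sd(x)
  if (is.null(r)) {
    if (s == 0) abort("constant signal: sample entropy undefined (SD = 0)")
    r <- r_frac * s
  }
  counts <- sampen_counts_cpp(as.numeric(x), as.integer(M), r)
  if (counts$B == 0) {
    warn("no template matches at length M; sample entropy undefined")
    value <- NA_real_
  } else if (counts$A == 0) {
    warn("no template pair extends to M+1 samples; returning +Inf")
    value <- Inf
  } else {
    value <- -log(counts$A / counts$B)
  }
  structure(value, A = counts$A, B = counts$B, r = r)
}

#' Select sample-entropy parameters by relative-error minimisation
#'
#' Evaluates every `(M, r)` candidate on a set of records and scores it with
#' the estimated relative error of the entropy estimate, using the binomial
#' approximation to the variance of the conditional probability `CP = A/B`:
#' `sigma = sqrt(CP (1 - CP) / B)` and metric
#' `max(sigma / CP, sigma / (CP |ln CP|))`. The pair minimising the median
#' metric across records wins; ties break toward smaller `M`, then larger `r`.
#'
#' @param records List of numeric series (one per trial).
#' @param M_grid Integer candidate template lengths.
#' @param r_grid Candidate tolerance fractions of the SD.
#' @return List with the selected `M`, `r_frac`, and tibble `grid` of the
#'   median metric per candidate.
#' @export
select_sen_params <- function(records, M_grid = 2:4,
                              r_grid = seq(0.03, 0.20, by = 0.01)) {
  if (!length(records)) abort("need at least one record")
  if (!length(M_grid) || !length(r_grid)) abort("parameter grids must be non-empty")
  grid <- tidyr::expand_grid(M = as.integer(M_grid), r_frac = r_grid)
  grid$metric <- purrr::pmap_dbl(grid, function(M, r_frac) {
    per_record <- vapply(records, function(x) {
      counts <- sampen_counts_cpp(as.numeric(x), M, r_frac * sd(x))
      if (counts$B == 0 || counts$A == 0) return(Inf)
      cp <- counts$A / counts$B
      sigma <- sqrt(cp * (1 - cp) / counts$B)
      if (cp >= 1) return(Inf)
      max(sigma / cp, sigma / (cp * abs(log(cp))))
    }, numeric(1))
    median(per_record)
  })
  if (all(!is.finite(grid$metric))) {
    abort("all (M, r) candidates degenerate: no extending template matches")
  }
  best <- grid |>
    arrange(.data$metric, .data$M, desc(.data$r_frac)) |>
    slice(1)
  list(M = best$M, r_frac = best$r_frac, grid = grid)
}

#' Average mutual information curve and first-minimum delay
#'
#' Estimates the mutual information (bits) between `x_t` and `x_{t+lag}` from
#' a two-dimensional histogram over `ceiling(N^(1/3))` equal-width bins per
#' margin, for lags `1..max_lag`.
#'
#' @param x Numeric series.
#' @param max_lag Largest lag evaluated; must be below `length(x) / 2`.
#' @param bins Number of marginal bins; default `ceiling(N^(1/3))`.
#' @return A tibble with columns `lag`, `ami`.
#' @export
average_mutual_information <- function(x, max_lag = 100, bins = NULL) {
  n <- length(x)
  if (max_lag >= n / 2) abort("max_lag must be below length(x)/2")
  if (sd(x) == 0) abort("constant signal: mutual information undefined")
  bins <- bins %||% ceiling(n^(1 / 3))
  breaks <- seq(min(x), max(x), length.out = bins + 1)
  bin <- cut(x, breaks, include.lowest = TRUE, labels = FALSE)
  ami <- vapply(seq_len(max_lag), function(lag) {
    bi <- bin[1:(n - lag)]
    bj <- bin[(1 + lag):n]
    joint <- tabulate(bi + bins * (bj - 1L), nbins = bins * bins)
    joint <- joint / sum(joint)
    pi_ <- tapply(joint, rep(seq_len(bins), times = bins), sum)
    pj_ <- tapply(joint, rep(seq_len(bins), each = bins), sum)
    pos <- joint > 0
    outer_p <- as.numeric(outer(pi_, pj_))[pos]
    sum(joint[pos] * log2(joint[pos] / outer_p))
  }, numeric(1))
  tibble(lag = seq_len(max_lag), ami = ami)
}

#' @rdname average_mutual_information
#' @details `first_minimum()` returns the first local minimum of the AMI
#'   curve. Histogram AMI estimates carry bin-level jitter, so the curve is
#'   first smoothed with a short centered moving average and a lag counts as
#'   a minimum only when it is the strict minimum of its `window`-lag
#'   neighbourhood. Noise-like records may have no minimum; the fallback is
#'   the first lag whose raw AMI drops below `AMI(1)/e`, then lag 1 with a
#'   warning when even that fails (flat curve).
#' @param ami_curve Tibble from `average_mutual_information()`.
#' @param window Half-width (lags) of the smoothing and detection window.
#' @return `first_minimum()`: an integer delay (samples).
#' @export
first_minimum <- function(ami_curve, window = 3) {
  a <- ami_curve$ami
  n <- length(a)
  sm <- vapply(seq_len(n), function(t) {
    mean(a[max(1, t - 2):min(n, t + 2)])
  }, numeric(1))
  for (t in 2:(n - 1)) {
    lo <- max(1, t - window); hi <- min(n, t + window)
    nbhd <- sm[lo:hi]
    if (sm[t] < sm[lo] && sum(nbhd == min(nbhd)) == 1 && sm[t] == min(nbhd)) {
      return(ami_curve$lag[t])
    }
  }
  drop <- which(a < a[1] / exp(1))
  if (length(drop)) {
    warn("no local AMI minimum; using first drop below AMI(1)/e")
    return(ami_curve$lag[drop[1]])
  }
  warn("flat AMI curve (noise-like record); returning lag 1")
  ami_curve$lag[1]
}

#' False nearest neighbours across embedding dimensions
#'
#' Kennel-style test for a sufficient embedding dimension: a neighbour in
#' dimension `m` is false when adding the `(m+1)`-th delay coordinate inflates
#' its distance by more than `Rtol`, or pushes it beyond `Atol` times the
#' attractor size (the series SD).
#'
#' @param x Numeric series.
#' @param tau Embedding delay, samples.
#' @param m_max Largest dimension tested.
#' @param Rtol,Atol Distance-ratio and loneliness thresholds.
#' @return Tibble with columns `m`, `fraction`.
#' @export
false_nearest_neighbors <- function(x, tau, m_max = 10, Rtol = 15, Atol = 2) {
  if ((m_max - 1) * tau >= length(x) / 2) {
    abort("too few delay vectors: reduce m_max or tau")
  }
  frac <- fnn_fractions_cpp(as.numeric(x), as.integer(tau), as.integer(m_max),
                            Rtol, Atol)
  tibble(m = seq_len(m_max), fraction = as.numeric(frac))
}

#' @rdname false_nearest_neighbors
#' @details `select_m()` returns the smallest dimension whose false-neighbour
#'   fraction drops below `threshold`; if none does (noise has no finite
#'   embedding), the largest tested dimension is returned with a warning.
#' @param fnn Tibble from `false_nearest_neighbors()`.
#' @param threshold "Near zero" fraction, default 1%.
#' @export
select_m <- function(fnn, threshold = 0.01) {
  ok <- which(!is.na(fnn$fraction) & fnn$fraction < threshold)
  if (length(ok)) return(fnn$m[ok[1]])
  warn("false-neighbour fraction never dropped below threshold; using m_max")
  max(fnn$m[!is.na(fnn$fraction)])
}

#' Delay-coordinate state-space reconstruction
#'
#' @param x Numeric series.
#' @param m Embedding dimension.
#' @param tau Delay, samples.
#' @return Matrix of `length(x) - (m-1) tau` rows; row `t` is
#'   `(x_t, x_{t+tau}, ..., x_{t+(m-1) tau})`.
#' @export
reconstruct <- function(x, m, tau) {
  nv <- length(x) - (m - 1) * tau
  if (nv < 1) abort("series too short for (m, tau)")
  sapply(seq_len(m), function(k) x[(1 + (k - 1) * tau):((k - 1) * tau + nv)],
         simplify = "array") |> matrix(nrow = nv)
}

#' Largest Lyapunov exponent (Rosenstein method)
#'
#' Embeds the series, pairs every point with its Euclidean nearest neighbour
#' outside a Theiler window, and tracks the mean log2 distance of the pairs
#' over time. The exponent is the least-squares slope of the first linear
#' stretch of this divergence curve, converted to bits per second by the
#' sampling rate. Positive values mean nearby states separate exponentially
#' (low local dynamic stability); a noiseless periodic signal gives ~0.
#'
#' @param x Numeric series.
#' @param m,tau Embedding dimension and delay.
#' @param fs Sampling rate, Hz (use 1 to report bits per sample/iteration).
#' @param fit_range Divergence steps (inclusive) used for the slope fit.
#' @param theiler Temporal neighbour-exclusion window; default `(m-1) tau`.
#' @return A `sway_lye` object: the exponent (bits s^-1), the divergence
#'   curve, and the fit; `tidy()`/`glance()`/`autoplot()` methods apply.
#' @export
lyapunov_rosenstein <- function(x, m, tau, fs, fit_range = c(0, 75),
                                theiler = (m - 1) * tau) {
  fit_lo <- as.integer(fit_range[1])
  fit_hi <- as.integer(fit_range[2])
  if (fit_lo >= fit_hi) abort("fit_range must be increasing")
  nv <- length(x) - (m - 1) * tau
  if (nv <= fit_hi + theiler + 1) {
    abort("not enough delay vectors beyond the fit window")
  }
  div <- rosenstein_divergence_cpp(as.numeric(x), as.integer(m), as.integer(tau),
                                   as.integer(theiler), fit_hi)
  curve <- tibble(
    step = 0:fit_hi,
    log2_dist = as.numeric(div$log2_dist),
    n_pairs = as.integer(div$n_pairs)
  )
  fit_pts <- curve |> filter(.data$step >= fit_lo, .data$step <= fit_hi,
                             is.finite(.data$log2_dist))
  if (nrow(fit_pts) < 2) abort("no valid neighbour pairs in the fit window")
  fit <- lm(log2_dist ~ step, data = fit_pts)
  structure(
    list(
      lye = unname(coef(fit)[2]) * fs,
      slope_per_step = unname(coef(fit)[2]),
      curve = curve, fit_range = c(fit_lo, fit_hi), fs = fs,
      m = m, tau = tau, theiler = theiler
    ),
    class = "sway_lye"
  )
}

#' @export
print.sway_lye <- function(x, ...) {
  cat(sprintf("<sway_lye> LyE = %.4f bits/s (m=%d, tau=%d, fit %d-%d steps @ %g Hz)\n",
              x$lye, x$m, x$tau, x$fit_range[1], x$fit_range[2], x$fs))
  invisible(x)
}

#' Detrended fluctuation analysis (DFA-1)
#'
#' Integrates the mean-centered series and, for each box size `n`, removes a
#' per-box linear trend and measures the root-mean-square residual `F(n)`.
#' The scaling exponent `alpha` is the slope of `log F(n)` against `log n`:
#' 0.5 for uncorrelated noise, 1.0 for 1/f (pink) noise, 1.5 for integrated
#' white (brown) noise.
#'
#' @param x Numeric series.
#' @param n_min,n_max Smallest and largest box size, samples.
#' @param n_scales Number of log-spaced box sizes.
#' @return A `sway_dfa` object with `alpha` and the `fluctuations` tibble;
#'   `tidy()`/`glance()`/`autoplot()` methods apply.
#' @export
dfa <- function(x, n_min = 10, n_max = 50, n_scales = 10) {
  n <- length(x)
  if (n < 4 * n_max) abort("series shorter than 4 * n_max")
  if (n_min < 4) abort("n_min must be >= 4")
  scales <- unique(round(exp(seq(log(n_min), log(n_max), length.out = n_scales))))
  if (length(scales) < 4) abort("fewer than 4 usable box sizes")
  y <- cumsum(x - mean(x))
  fl <- vapply(scales, function(s) {
    nb <- floor(n / s)
    ymat <- matrix(y[seq_len(nb * s)], nrow = s)
    X <- cbind(1, seq_len(s))
    resid <- ymat - X %*% solve(crossprod(X), crossprod(X, ymat))
    sqrt(mean(resid^2))
  }, numeric(1))
  fit <- lm(log(fl) ~ log(scales))
  structure(
    list(alpha = unname(coef(fit)[2]),
         fluctuations = tibble(n = scales, fn = fl)),
    class = "sway_dfa"
  )
}

#' @export
print.sway_dfa <- function(x, ...) {
  cat(sprintf("<sway_dfa> alpha = %.4f over box sizes %d-%d (%d scales)\n",
              x$alpha, min(x$fluctuations$n), max(x$fluctuations$n),
              nrow(x$fluctuations)))
  invisible(x)
}

#' Map a frequency band to DFA box sizes
#'
#' Box sizes are taken as the period equivalents of the band edges
#' (`n = fs / f`), so the scaling exponent reflects fluctuations at the
#' requested frequencies only. Results are clipped to the DFA validity range
#' `[4, N/4]` when `n` is supplied.
#'
#' @param band Frequency band `c(f_lo, f_hi)`, Hz.
#' @param fs Sampling rate, Hz.
#' @param n Optional series length for clipping.
#' @return List with `n_min`, `n_max`.
#' @export
dfa_band_to_scales <- function(band, fs, n = NULL) {
  f_lo <- band[1]; f_hi <- band[2]
  if (!(f_lo > 0 && f_lo < f_hi && f_hi <= fs / 2)) {
    abort("need 0 < f_lo < f_hi <= fs/2")
  }
  n_min <- max(4, round(fs / f_hi))
  n_max <- round(fs / f_lo)
  if (!is.null(n)) n_max <- min(n_max, floor(n / 4))
  if (n_min >= n_max) abort("band maps to an empty box-size range")
  list(n_min = n_min, n_max = n_max)
}

#' Per-axis complexity profile of a preprocessed signal
#'
#' Applies the four sway measures with the per-axis parameters from the
#' configuration (sample-entropy tolerance fraction and embedding delay
#' differ between ML and AP).
#'
#' @param x Preprocessed acceleration series (m s^-2) at `cfg$fs_target`.
#' @param axis `"ML"` or `"AP"`.
#' @param cfg A [sway_config()].
#' @return One-row tibble with columns `axis`, `rms`, `sen`, `lye`,
#'   `alpha_dfa`.
#' @export
complexity_profile <- function(x, axis = c("ML", "AP"), cfg = sway_config()) {
  axis <- match.arg(axis)
  scales <- dfa_band_to_scales(cfg$dfa_band, cfg$fs_target, length(x))
  sen <- sample_entropy(x, M = cfg$sen_M, r_frac = cfg$sen_r_frac[[axis]])
  lye <- lyapunov_rosenstein(x, m = cfg$embed_m, tau = cfg$embed_tau[[axis]],
                             fs = cfg$fs_target, fit_range = cfg$lye_fit_range)
  alpha <- dfa(x, scales$n_min, scales$n_max, cfg$dfa_n_scales)
  if (is.finite(alpha$alpha) && (alpha$alpha < 0.2 || alpha$alpha > 2.0)) {
    warn(sprintf("alpha-DFA = %.2f outside the typical (0.2, 2.0) range", alpha$alpha))
  }
  tibble(
    axis = axis,
    rms = rms_sway(x, cfg$unit_scale),
    sen = as.numeric(sen),
    lye = lye$lye,
    alpha_dfa = alpha$alpha
  )
}
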