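#' Colored noise by spectral synthesis
#'
#' Draws a unit-variance series whose power spectrum falls off as
#' `f^-beta`: amplitudes proportional to `f^(-beta/2)` with uniform random
#' phases, inverse-transformed to the time domain. `beta = 0` is white noise,
#' `beta = 1` pink, `beta = 2` brown-like.
#'
#' @param n Series length (>= 64).
#' @param beta Spectral exponent in `[0, 2]`.
#' @param seed Integer seed (deterministic output).
#' @return Numeric series, mean 0 and SD 1.
#' @export
gen_colored_noise <- function(n, beta, seed = 1) {
  if (n < 64) abort("n must be >= 64")
  if (beta < 0 || beta > 2) abort("beta must lie in [0, 2]")
  with_stream(seed, "colored", beta, n, expr = spectral_noise(n, function(f) f^(-beta / 2)))
}

# Spectral synthesis with an arbitrary amplitude profile over normalized
# frequency (cycles/sample in (0, 0.5]); unit variance output.
spectral_noise <- function(n, amp_fun) {
  nf <- floor(n / 2)
  f <- seq_len(nf) / n
  amp <- amp_fun(f)
  amp[!is.finite(amp)] <- 0
  phases <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phases)
  if (n %% 2 == 0) spec[nf] <- complex(real = amp[nf] * sign(cos(phases[nf])), imaginary = 0)
  full <- c(complex(real = 0), spec,
            Conj(rev(spec[seq_len(nf - 1 + n %% 2)])))
  x <- Re(fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- sd(x)
  if (s == 0) abort("degenerate spectrum: zero variance")
  x / s
}

#' Exact oracle signals for estimator validation
#'
#' @param kind One of `"sine"` (unit amplitude), `"logistic_map"` (r = 4,
#'   seeded start, 100-sample transient discarded), `"periodic_pattern"`
#'   (noiseless repetition of a fixed 5-sample pattern), `"brown"`
#'   (cumulative sum of white noise).
#' @param n Series length (>= 100).
#' @param seed Integer seed for the stochastic kinds.
#' @param f,fs Sine frequency and sampling rate, Hz.
#' @return Numeric series of length `n`.
#' @export
gen_oracle_signals <- function(kind = c("sine", "logistic_map", "periodic_pattern", "brown"),
                               n, seed = 1, f = 1, fs = 100) {
  kind <- match.arg(kind)
  if (n < 100) abort("n must be >= 100")
  switch(kind,
    sine = sin(2 * pi * f * (0:(n - 1)) / fs),
    logistic_map = with_stream(seed, "logistic", expr = {
      x <- runif(1, 0.1, 0.9)
      out <- numeric(n + 100)
      for (i in seq_along(out)) {
        x <- 4 * x * (1 - x)
        out[i] <- x
      }
      out[101:(n + 100)]
    }),
    periodic_pattern = rep_len(c(0.2, 0.9, 0.4, 1.0, 0.6), n),
    brown = with_stream(seed, "brown", expr = cumsum(rnorm(n)))
  )
}

#' Tunable knobs of the synthetic sway generator
#'
#' Defaults describe a plausible quiet-stance trunk recording of a
#' normal-weight adolescent on a firm surface: a long-range-correlated core
#' concentrated in the 0.5-10 Hz sway band, a low-frequency postural
#' oscillation, horizontal RMS near 0.035-0.037 m s^-2 (35-37 mm s^-2), a
#' broadband sensor noise floor, and a few degrees of sensor tilt.
#'
#' @param beta Spectral exponent of the band-limited colored core, `[0, 2]`.
#' @param periodic_weight Fraction of sway variance contributed by the
#'   low-frequency oscillation, `[0, 1]`. Higher values make the signal more
#'   repeatable (lower sample entropy).
#' @param amp Named RMS targets (m s^-2) for the `ML` and `AP` sway, before
#'   the noise floor is added.
#' @param noise_floor SD (m s^-2) of white sensor noise added to all axes;
#'   mostly removed by the 0.3-10 Hz band-pass. Its in-band remainder makes
#'   the signal less regular (higher sample entropy) and flattens the in-band
#'   spectrum (lower alpha-DFA).
#' @param tilt_deg Sensor mounting tilt, degrees `c(pitch, roll)`.
#' @param osc_freq Frequency of the postural oscillation, Hz.
#' @return A `sway_knobs` list.
#' @export
sway_knobs <- function(beta = 1.1, periodic_weight = 0.25,
                       amp = c(ML = 0.035, AP = 0.037), noise_floor = 0.012,
                       tilt_deg = c(pitch = 4, roll = 2), osc_freq = 0.7) {
  if (beta < 0 || beta > 2) abort("beta must lie in [0, 2]")
  if (periodic_weight < 0 || periodic_weight > 1) abort("periodic_weight in [0, 1]")
  if (any(amp <= 0)) abort("amp must be positive")
  if (noise_floor < 0) abort("noise_floor must be >= 0")
  stopifnot(all(c("ML", "AP") %in% names(amp)))
  structure(list(beta = beta, periodic_weight = periodic_weight,
                 amp = amp[c("ML", "AP")], noise_floor = noise_floor,
                 tilt_deg = tilt_deg, osc_freq = osc_freq),
            class = "sway_knobs")
}

#' Generate one synthetic tri-axial sway trial
#'
#' Horizontal sway per axis is a band-limited (0.5-10 Hz) colored-noise core
#' mixed with a low-frequency oscillation, scaled to the axis RMS target.
#' The pair is embedded in a sensor frame tilted by `tilt_deg` with gravity
#' on the vertical axis, and white sensor noise is added to all three
#' channels — so the preprocessing chain (tilt-correction, band-pass) has
#' real work to do before the measures see the signal.
#'
#' @param knobs A [sway_knobs()] object.
#' @param duration_s,fs Trial length (s) and acquisition rate (Hz).
#' @param seed Integer seed; identical seeds give identical trials.
#' @param g Gravitational acceleration, m s^-2.
#' @param subject_id,group,condition,visit Metadata passed to the recording.
#' @return A [sway_recording()].
#' @export
gen_sway_trial <- function(knobs = sway_knobs(), duration_s = 60, fs = 500,
                           seed = 1, g = 9.81, subject_id = "S01",
                           group = NA_character_, condition = NA_character_,
                           visit = NA_integer_) {
  n <- as.integer(round(duration_s * fs))
  pw <- knobs$periodic_weight
  horiz <- lapply(c(ML = "ML", AP = "AP"), function(axis) {
    core <- with_stream(seed, "core", axis, expr = {
      spectral_noise(n, function(f) {
        hz <- f * fs
        ifelse(hz >= 0.5 & hz <= 10, pmax(hz, 0.5)^(-knobs$beta / 2), 0)
      })
    })
    phase <- with_stream(seed, "phase", axis, expr = runif(1, 0, 2 * pi))
    osc <- sqrt(2) * sin(2 * pi * knobs$osc_freq * (0:(n - 1)) / fs + phase)
    s <- sqrt(1 - pw) * core + sqrt(pw) * osc
    s / sd(s) * knobs$amp[[axis]]
  })
  body <- rbind(horiz$ML, horiz$AP, rep(g, n))
  pitch <- knobs$tilt_deg[[1]] * pi / 180
  roll <- knobs$tilt_deg[[2]] * pi / 180
  rot_x <- rbind(c(1, 0, 0), c(0, cos(pitch), -sin(pitch)), c(0, sin(pitch), cos(pitch)))
  rot_y <- rbind(c(cos(roll), 0, -sin(roll)), c(0, 1, 0), c(sin(roll), 0, cos(roll)))
  sensor <- t(rot_x) %*% t(rot_y) %*% body
  noise <- with_stream(seed, "floor", expr = matrix(rnorm(3 * n, 0, knobs$noise_floor), nrow = 3))
  sensor <- sensor + noise
  sway_recording(tibble(ml = sensor[1, ], ap = sensor[2, ], vert = sensor[3, ]),
                 fs_in = fs, subject_id = subject_id, group = group,
                 condition = condition, visit = visit)
}

#' Specification of a synthetic study cohort
#'
#' Describes a two-group, two-condition, two-visit design. Group and
#' condition effects act multiplicatively on the generator knobs — not on the
#' measures — so recovering them through the pipeline is a genuine inverse
#' problem. The default effect directions mirror what is reported for
#' overweight adolescents: the "YO" arm is more persistent (higher `beta`,
#' which simultaneously lowers sample entropy, raises alpha-DFA and raises
#' the local divergence rate), more repeatable (higher `periodic_weight`,
#' further lowering sample entropy) and sways harder in AP (`amp_AP`). Foam
#' standing amplifies sway amplitude and shifts the structure knobs the same
#' way.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param base Baseline [sway_knobs()] (a normal-weight subject, firm floor).
#' @param group_factors,condition_factors Named multiplicative factors on
#'   knobs (`beta`, `periodic_weight`, `amp_ML`, `amp_AP`, `noise_floor`)
#'   applied to the YO group / foam condition.
#' @param subject_sd,retest_jitter Log-normal SDs of the between-subject knob
#'   variation (shared by both visits, which is what makes the measures
#'   reliable) and of the per-visit knob perturbation (which is what limits
#'   test-retest agreement).
#' @param visits Number of visits.
#' @param duration_s,fs Trial length and acquisition rate.
#' @param seed Base seed for the whole cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 19,
                        base = sway_knobs(),
                        group_factors = c(beta = 1.12, periodic_weight = 1.45,
                                          amp_AP = 1.25),
                        condition_factors = c(amp_ML = 1.5, amp_AP = 1.45,
                                              beta = 1.07, periodic_weight = 1.25),
                        subject_sd = 0.15, retest_jitter = 0.05,
                        visits = 2, duration_s = 60, fs = 500, seed = 1) {
  if (n_per_group < 2) abort("n_per_group must be >= 2")
  if (any(c(group_factors, condition_factors) <= 0)) abort("effect factors must be > 0")
  structure(list(n_per_group = n_per_group, base = base,
                 group_factors = group_factors,
                 condition_factors = condition_factors,
                 subject_sd = subject_sd, retest_jitter = retest_jitter,
                 visits = visits, duration_s = duration_s, fs = fs, seed = seed),
            class = "cohort_spec")
}

apply_knob_factors <- function(knobs, factors) {
  for (nm in names(factors)) {
    val <- factors[[nm]]
    if (nm == "amp_ML") knobs$amp[["ML"]] <- knobs$amp[["ML"]] * val
    else if (nm == "amp_AP") knobs$amp[["AP"]] <- knobs$amp[["AP"]] * val
    else knobs[[nm]] <- knobs[[nm]] * val
  }
  knobs$beta <- min(knobs$beta, 2)
  knobs$periodic_weight <- min(knobs$periodic_weight, 0.95)
  knobs
}

#' Generate a full synthetic study cohort
#'
#' Draws per-subject baseline knobs, applies the group and condition factors
#' plus per-visit retest jitter, and generates every trial. The returned
#' truth table records the realized knob values for recovery tests.
#'
#' @param spec A [cohort_spec()].
#' @return List with `recordings` (list of [sway_recording()]) and `truth`
#'   (tibble: one row per trial with the realized knobs).
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- tibble(
    subject_id = sprintf("S%02d", seq_len(2 * spec$n_per_group)),
    group = rep(c("YO", "YN"), each = spec$n_per_group)
  )
  trials <- tidyr::expand_grid(subjects,
                               condition = c("firm", "foam"),
                               visit = seq_len(spec$visits))
  jitter_knob <- function(knobs, sds) {
    mult <- exp(rnorm(4, 0, sds))
    knobs$beta <- min(knobs$beta * mult[1], 2)
    knobs$periodic_weight <- min(knobs$periodic_weight * mult[2], 0.95)
    knobs$amp <- knobs$amp * mult[3]
    knobs$noise_floor <- knobs$noise_floor * mult[4]
    knobs
  }
  rows <- purrr::pmap(trials, function(subject_id, group, condition, visit) {
    knobs <- with_stream(spec$seed, "subject", subject_id,
                         expr = jitter_knob(spec$base, spec$subject_sd))
    if (group == "YO") knobs <- apply_knob_factors(knobs, spec$group_factors)
    if (condition == "foam") knobs <- apply_knob_factors(knobs, spec$condition_factors)
    knobs <- with_stream(spec$seed, "visit", subject_id, visit,
                         expr = jitter_knob(knobs, spec$retest_jitter))
    rec <- gen_sway_trial(
      knobs, duration_s = spec$duration_s, fs = spec$fs,
      seed = substream_seed(spec$seed, "trial", subject_id, condition, visit),
      subject_id = subject_id, group = group, condition = condition, visit = visit
    )
    list(rec = rec,
         truth = tibble(subject_id = subject_id, group = group,
                        condition = condition, visit = visit,
                        beta = knobs$beta, periodic_weight = knobs$periodic_weight,
                        amp_ml = knobs$amp[["ML"]], amp_ap = knobs$amp[["AP"]],
                        noise_floor = knobs$noise_floor))
  })
  list(recordings = purrr::map(rows, "rec"),
       truth = purrr::map(rows, "truth") |> list_rbind())
}

#' Write a generated cohort as text trials plus a metadata CSV
#'
#' Produces the on-disk layout [run_pipeline()] consumes: one delimited text
#' file per trial (readable by [read_imu_text()]) and `metadata.csv` mapping
#' files to subject, group, condition and visit.
#'
#' @param cohort Result of [gen_cohort()].
#' @param dir Output directory (created if needed).
#' @param dialect Text dialect, see [imu_dialect()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = imu_dialect()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- purrr::map(cohort$recordings, function(rec) {
    file <- sprintf("%s_%s_v%d.txt", rec$meta$subject_id, rec$meta$condition,
                    rec$meta$visit)
    write_imu_text(rec, file.path(dir, file), dialect)
    mutate(rec$meta, file = file, fs_in = rec$fs_in)
  }) |> list_rbind()
  readr::write_csv(meta, file.path(dir, "metadata.csv"))
  invisible(dir)
}
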