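#' Run configuration for the sway-analysis pipeline
#'
#' Builds the configuration object consumed by every pipeline stage. Defaults
#' reproduce the fixed analysis constants of the trunk-accelerometry protocol
#' the package implements: 500 Hz acquisition downsampled to 100 Hz, middle
#' 50 s crop (5,000 samples), 0.3-10 Hz zero-phase Butterworth band-pass of
#' 4th order, a five-window standard-deviation artifact screen with a fivefold
#' ratio bound, sample entropy with `M = 3` and a tolerance of 0.07 (ML) or
#' 0.06 (AP) times the series SD, delay embedding with `m = 4` and `tau = 17`
#' (ML) or `20` (AP) samples, a 0-75 sample divergence fit for the Lyapunov
#' exponent, and DFA restricted to box sizes equivalent to 2-10 Hz.
#'
#' @param ... Named overrides for any default field, e.g. `sen_M = 2`,
#'   `band = c(0.5, 8)`. Unknown names are an error.
#'
#' @return A `sway_config` list with fields:
#' \describe{
#'   \item{fs_target}{analysis sampling rate, Hz.}
#'   \item{crop_s}{central crop length, s.}
#'   \item{band, filter_order}{band-pass corners (Hz) and order of the
#'     band-pass transfer function (applied forward-backward).}
#'   \item{sen_M, sen_r_frac}{sample-entropy template length and per-axis
#'     tolerance fraction of the SD (named `ML`, `AP`).}
#'   \item{embed_m, embed_tau}{embedding dimension and per-axis delay.}
#'   \item{lye_fit_range}{divergence-curve fit window, samples.}
#'   \item{dfa_band}{frequency band (Hz) mapped to DFA box sizes.}
#'   \item{artifact_windows, artifact_window_s, artifact_ratio}{screen layout
#'     and maximum allowed max/min SD ratio.}
#'   \item{bootstrap_B, seed, icc_poor_threshold, alpha_level, unit_scale}{
#'     bootstrap resamples, base RNG seed, reliability-gate threshold,
#'     significance level, and the m s^-2 to mm s^-2 report factor.}
#' }
#' @export
#' @examples
#' cfg <- sway_config()
#' cfg$crop_s * cfg$fs_target  # 5000 analysis samples
#' sway_config(sen_M = 2)$sen_M
sway_config <- function(...) {
  defaults <- list(
    fs_in = 500,
    fs_target = 100,
    crop_s = 50,
    band = c(0.3, 10),
    filter_order = 4,
    sen_M = 3L,
    sen_r_frac = c(ML = 0.07, AP = 0.06),
    embed_m = 4L,
    embed_tau = c(ML = 17L, AP = 20L),
    lye_fit_range = c(0L, 75L),
    dfa_band = c(2, 10),
    dfa_n_scales = 10L,
    artifact_windows = 5L,
    artifact_window_s = 10,
    artifact_ratio = 5.0,
    bootstrap_B = 10000L,
    seed = 20220428L,
    icc_poor_threshold = 0.40,
    alpha_level = 0.05,
    unit_scale = 1000
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
    }
    defaults[names(overrides)] <- overrides
  }
  cfg <- structure(defaults, class = "sway_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  check <- function(ok, field, bound) {
    if (!ok) abort(sprintf("config field '%s' out of range: %s", field, bound))
  }
  check(cfg$fs_target > 0, "fs_target", "must be > 0")
  check(cfg$fs_in >= cfg$fs_target, "fs_in", "must be >= fs_target")
  check(length(cfg$band) == 2 && cfg$band[1] > 0 && cfg$band[1] < cfg$band[2],
        "band", "0 < low < high")
  check(cfg$band[2] < cfg$fs_target / 2, "band",
        sprintf("high corner must be below the Nyquist rate %g Hz", cfg$fs_target / 2))
  check(cfg$filter_order >= 2 && cfg$filter_order %% 2 == 0, "filter_order",
        "even order >= 2")
  check(cfg$crop_s > 0, "crop_s", "must be > 0")
  check(cfg$sen_M >= 1, "sen_M", "must be >= 1")
  check(all(cfg$sen_r_frac > 0 & cfg$sen_r_frac < 1), "sen_r_frac", "in (0, 1)")
  check(cfg$embed_m >= 2, "embed_m", "must be >= 2")
  check(all(cfg$embed_tau >= 1), "embed_tau", "must be >= 1")
  check(length(cfg$dfa_band) == 2 && cfg$dfa_band[1] > 0 &&
          cfg$dfa_band[1] < cfg$dfa_band[2] && cfg$dfa_band[2] <= cfg$fs_target / 2,
        "dfa_band", "0 < low < high <= Nyquist")
  check(cfg$artifact_ratio > 1, "artifact_ratio", "must be > 1")
  check(cfg$alpha_level > 0 && cfg$alpha_level < 1, "alpha_level", "in (0, 1)")
  check(cfg$unit_scale > 0, "unit_scale", "must be > 0")
  invisible(cfg)
}

#' Load a run configuration from a YAML file
#'
#' Fields absent from the file fall back to the protocol defaults of
#' [sway_config()]. The full effective configuration is echoed to the log so a
#' run's constants are always visible in its transcript.
#'
#' @param path Path to a YAML file; an empty file yields all defaults.
#' @param quiet Suppress the config echo.
#' @return A `sway_config` object.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  raw <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  cfg <- do.call(sway_config, raw)
  if (!quiet) {
    flat <- vapply(cfg, function(x) paste(x, collapse = ","), character(1))
    sway_log("INFO", "effective config: ",
             paste(names(flat), flat, sep = "=", collapse = " "))
  }
  cfg
}

#' @export
print.sway_config <- function(x, ...) {
  cat("<sway_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}
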