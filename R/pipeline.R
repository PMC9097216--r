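measure_units <- c(rms = "mm.s-2", sen = "bit", lye = "bit.s-1", alpha_dfa = "")

#' Preprocess and measure every trial of a cohort directory
#'
#' Reads `metadata.csv` plus the trial files it names, preprocesses each
#' trial and computes the per-axis complexity profile, returning the
#' long-format study table together with the artifact verdicts.
#'
#' @param input_dir Directory holding `metadata.csv` and trial text files.
#' @param cfg A [sway_config()].
#' @param dialect Text dialect for [read_imu_text()].
#' @param measures Character subset of `c("rms", "sen", "lye", "alpha_dfa")`
#'   to compute (all by default; restricting speeds up simulation studies).
#' @return List with `table` (study table tibble), `verdicts` (one row per
#'   trial: metadata, `pass`, `ratio`).
#' @export
measure_cohort <- function(input_dir, cfg = sway_config(), dialect = imu_dialect(),
                           measures = c("rms", "sen", "lye", "alpha_dfa")) {
  measures <- match.arg(measures, several.ok = TRUE)
  meta_path <- file.path(input_dir, "metadata.csv")
  if (!file.exists(meta_path)) abort(sprintf("metadata.csv not found in %s", input_dir))
  meta <- readr::read_csv(meta_path, col_types = readr::cols())
  out <- purrr::pmap(meta, function(subject_id, group, condition, visit, file, ...) {
    fs_in <- list(...)$fs_in %||% cfg$fs_in
    rec <- read_imu_text(file.path(input_dir, file), dialect, fs_in = fs_in,
                         subject_id = subject_id, group = group,
                         condition = condition, visit = visit)
    pre <- preprocess_trial(rec, cfg)
    profiles <- purrr::map(
      c("ML", "AP"),
      function(ax) trial_measures(pre$signals[[tolower(ax)]], ax, cfg, measures)
    ) |> list_rbind()
    rows <- profiles |> mutate(subject = subject_id, group = group,
                               condition = condition, visit = visit,
                               .before = 1)
    verdict <- tibble(subject = subject_id, group = group, condition = condition,
                      visit = visit, file = file, pass = pre$verdict$pass,
                      ratio = pre$verdict$ratio)
    list(rows = rows, verdict = verdict)
  })
  list(table = purrr::map(out, "rows") |> list_rbind(),
       verdicts = purrr::map(out, "verdict") |> list_rbind())
}

trial_measures <- function(x, axis, cfg, measures) {
  vals <- c()
  if ("rms" %in% measures) vals["rms"] <- rms_sway(x, cfg$unit_scale)
  if ("sen" %in% measures) {
    vals["sen"] <- as.numeric(sample_entropy(x, cfg$sen_M, cfg$sen_r_frac[[axis]]))
  }
  if ("lye" %in% measures) {
    vals["lye"] <- lyapunov_rosenstein(x, cfg$embed_m, cfg$embed_tau[[axis]],
                                       fs = cfg$fs_target,
                                       fit_range = cfg$lye_fit_range)$lye
  }
  if ("alpha_dfa" %in% measures) {
    sc <- dfa_band_to_scales(cfg$dfa_band, cfg$fs_target, length(x))
    vals["alpha_dfa"] <- dfa(x, sc$n_min, sc$n_max, cfg$dfa_n_scales)$alpha
  }
  tibble(axis = axis, measure = names(vals), value = unname(vals),
         units = unname(measure_units[names(vals)]))
}

#' Test-retest reliability grid for a study table
#'
#' Computes ICC(1,1) between visit 1 and visit 2 for every
#' measure x axis x group x condition cell.
#'
#' @param table Study table (long format, visits 1 and 2 complete).
#' @return Tibble with `measure`, `axis`, `group`, `condition`, `icc`,
#'   `band`.
#' @export
icc_report <- function(table) {
  wide <- table |>
    filter(is.finite(.data$value)) |>
    tidyr::pivot_wider(id_cols = c("subject", "group", "condition", "axis", "measure"),
                       names_from = "visit", values_from = "value",
                       names_prefix = "v")
  if (!all(c("v1", "v2") %in% names(wide))) abort("need visits 1 and 2 for ICC")
  wide |>
    filter(is.finite(.data$v1), is.finite(.data$v2)) |>
    group_by(.data$measure, .data$axis, .data$group, .data$condition) |>
    reframe(icc_1_1(.data$v1, .data$v2)[c("icc", "band")])
}

#' Post-hoc pairwise comparisons for one measure x axis
#'
#' Builds the comparison family the inference layer reports after a
#' significant ANOVA effect: group contrasts within each condition
#' (independent t on subject means) and condition contrasts within each
#' group (paired t), Benjamini-Hochberg adjusted as a single family. When
#' `pool_visits` is `TRUE` (the default when no visit term is significant),
#' values are first averaged across visits per subject.
#'
#' @param data Long data for one measure x axis: `subject`, `group`,
#'   `condition`, `visit`, `value`.
#' @param alpha FDR level.
#' @param pool_visits Average across visits first?
#' @return Tibble of comparisons with BH-adjusted decisions.
#' @export
posthoc_report <- function(data, alpha = 0.05, pool_visits = TRUE) {
  d <- if (pool_visits) {
    data |> group_by(.data$subject, .data$group, .data$condition) |>
      summarise(value = mean(.data$value), .groups = "drop") |>
      mutate(visit = NA_integer_)
  } else {
    data |> select("subject", "group", "condition", "visit", "value")
  }
  one_stratum <- function(dv, label) {
    group_comps <- dv |> group_by(.data$condition) |>
      reframe({
        yo <- .data$value[.data$group == "YO"]
        yn <- .data$value[.data$group == "YN"]
        tt <- stats::t.test(yo, yn, var.equal = TRUE)
        tibble(contrast = "YO - YN", estimate = mean(yo) - mean(yn),
               t = unname(tt$statistic), p = tt$p.value)
      }) |>
      mutate(within = trimws(paste("condition", .data$condition, label))) |>
      select(-"condition")
    cond_comps <- dv |> group_by(.data$group) |>
      reframe({
        wide <- tidyr::pivot_wider(pick(everything()), id_cols = "subject",
                                   names_from = "condition", values_from = "value")
        tt <- stats::t.test(wide$foam, wide$firm, paired = TRUE)
        tibble(contrast = "foam - firm", estimate = mean(wide$foam - wide$firm),
               t = unname(tt$statistic), p = tt$p.value)
      }) |>
      mutate(within = trimws(paste("group", .data$group, label))) |>
      select(-"group")
    bind_rows(group_comps, cond_comps)
  }
  comps <- if (pool_visits) {
    one_stratum(d, "")
  } else {
    purrr::map(unique(d$visit), function(v) {
      one_stratum(filter(d, .data$visit == v), sprintf("visit %s", v))
    }) |> list_rbind()
  }
  comps |>
    mutate(family = "pairwise") |>
    posthoc_pairwise_bh(alpha = alpha) |>
    select("within", "contrast", "estimate", "t", "p", "p_adj", "significant")
}

#' Run the complete study analysis
#'
#' Orchestrates the full chain on a cohort directory: preprocessing with the
#' artifact screen (a failing trial excludes its whole subject, as in the
#' study protocol), per-trial complexity profiles, the ICC reliability grid
#' with the poor-reliability gate, and — for every retained measure x axis —
#' the three-way mixed ANOVA on `ln(x+1)`-transformed values followed by
#' Benjamini-Hochberg post-hoc comparisons (visits pooled when no visit term
#' reaches `cfg$alpha_level`). All reports plus a run manifest are written to
#' `out_dir` as CSV/YAML when given.
#'
#' @param input_dir Cohort directory (see [write_cohort()]).
#' @param cfg A [sway_config()].
#' @param out_dir Optional output directory.
#' @param dialect Text dialect of the trial files.
#' @param measures Measures to compute (see [measure_cohort()]).
#' @return List: `table`, `icc`, `anova`, `posthoc`, `manifest`.
#' @export
run_pipeline <- function(input_dir, cfg = sway_config(), out_dir = NULL,
                         dialect = imu_dialect(),
                         measures = c("rms", "sen", "lye", "alpha_dfa")) {
  measured <- measure_cohort(input_dir, cfg, dialect, measures)
  verdicts <- measured$verdicts
  bad_subjects <- unique(verdicts$subject[!verdicts$pass])
  exclusions <- tibble(
    subject = bad_subjects,
    reason = sprintf("windowed-SD artifact screen failed (ratio > %g)", cfg$artifact_ratio)
  )
  for (s in bad_subjects) {
    sway_log("WARN", sprintf("excluding subject %s: artifact screen failed", s))
  }
  table <- measured$table |> filter(!.data$subject %in% bad_subjects)
  if (!nrow(table)) abort("empty cohort after artifact exclusions")
  icc <- icc_report(table)
  gated <- reliability_gate(icc, cfg$icc_poor_threshold)
  if (nrow(gated)) {
    sway_log("WARN", "poor reliability, not inferentially tested: ",
             paste(gated$measure, gated$axis, collapse = "; "))
  }
  combos <- table |> distinct(.data$measure, .data$axis) |>
    anti_join(gated, by = c("measure", "axis"))
  anova_rows <- list()
  posthoc_rows <- list()
  for (i in seq_len(nrow(combos))) {
    ms <- combos$measure[i]; ax <- combos$axis[i]
    d <- table |> filter(.data$measure == ms, .data$axis == ax,
                         is.finite(.data$value)) |>
      mutate(value = log1_transform(.data$value))
    fit <- mixed_anova_2x2x2(d)
    anova_rows[[paste(ms, ax)]] <- tidy(fit) |>
      mutate(measure = ms, axis = ax, .before = 1)
    visit_p <- fit$table |> filter(grepl("visit", .data$effect)) |> pull(p)
    ph <- posthoc_report(d, alpha = cfg$alpha_level,
                         pool_visits = all(visit_p > cfg$alpha_level))
    posthoc_rows[[paste(ms, ax)]] <- ph |> mutate(measure = ms, axis = ax, .before = 1)
  }
  anova_tbl <- list_rbind(anova_rows)
  posthoc_tbl <- list_rbind(posthoc_rows)
  manifest <- list(
    seed = cfg$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = lapply(unclass(cfg), function(x) if (is.numeric(x)) unname(x) else x),
    inputs = purrr::pmap(verdicts, function(subject, condition, visit, file, pass, ratio, ...) {
      list(file = file, subject = subject, condition = condition,
           visit = visit, pass = pass, ratio = round(ratio, 4))
    }),
    excluded_subjects = purrr::pmap(exclusions, function(subject, reason) {
      list(subject = subject, reason = reason)
    }),
    gated_measures = purrr::pmap(gated, function(measure, axis, min_icc, worst_cell) {
      list(measure = measure, axis = axis, min_icc = round(min_icc, 4),
           reason = sprintf("poor test-retest reliability (ICC <= %g) in cell %s",
                            cfg$icc_poor_threshold, worst_cell))
    })
  )
  result <- list(table = table, icc = icc, anova = anova_tbl,
                 posthoc = posthoc_tbl, manifest = manifest,
                 verdicts = verdicts, exclusions = exclusions)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_measures(table, file.path(out_dir, "measures.csv"))
    readr::write_csv(icc, file.path(out_dir, "icc.csv"))
    readr::write_csv(anova_tbl, file.path(out_dir, "anova.csv"))
    if (nrow(posthoc_tbl)) readr::write_csv(posthoc_tbl, file.path(out_dir, "posthoc.csv"))
    manifest$outputs <- file.path(out_dir, c("measures.csv", "icc.csv", "anova.csv",
                                             if (nrow(posthoc_tbl)) "posthoc.csv"))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    result$manifest <- manifest
  }
  result
}
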