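#' Construct a raw tri-axial sway recording
#'
#' @param acc A data frame (or tibble) with numeric columns `ml`, `ap`, `vert`:
#'   acceleration in m s^-2 along the mediolateral, anteriorposterior and
#'   longitudinal sensor axes, one sample per row.
#' @param fs_in Acquisition sampling rate, Hz.
#' @param subject_id,group,condition,visit Trial metadata; `group` is one of
#'   `"YO"`/`"YN"`, `condition` one of `"firm"`/`"foam"`, `visit` 1 or 2.
#' @return A `sway_recording` object.
#' @export
sway_recording <- function(acc, fs_in = 500, subject_id = NA_character_,
                           group = NA_character_, condition = NA_character_,
                           visit = NA_integer_) {
  acc <- as_tibble(acc)
  stopifnot(all(c("ml", "ap", "vert") %in% names(acc)))
  acc <- acc[c("ml", "ap", "vert")]
  if (!all(vapply(acc, is.numeric, logical(1)))) abort("acceleration columns must be numeric")
  if (fs_in <= 0) abort("fs_in must be positive")
  if (!is.na(group) && !group %in% c("YO", "YN")) abort("group must be 'YO' or 'YN'")
  if (!is.na(condition) && !condition %in% c("firm", "foam")) {
    abort("condition must be 'firm' or 'foam'")
  }
  structure(
    list(
      acc = acc, fs_in = fs_in,
      meta = tibble(
        subject_id = as.character(subject_id), group = group,
        condition = condition, visit = as.integer(visit)
      ),
      duration = nrow(acc) / fs_in
    ),
    class = "sway_recording"
  )
}

#' @export
print.sway_recording <- function(x, ...) {
  cat(sprintf(
    "<sway_recording> %s | %s %s visit %s | %d samples @ %g Hz (%.1f s)\n",
    x$meta$subject_id, x$meta$group %|na|% "?", x$meta$condition %|na|% "?",
    x$meta$visit %|na|% "?", nrow(x$acc), x$fs_in, x$duration
  ))
  invisible(x)
}

#' Read a delimited IMU text export
#'
#' Reads one trial from a plain-text accelerometer export (one sample per
#' row). The vendor schema is not fixed, so the column positions, delimiter
#' and unit scale are declared through `dialect`. Rows with non-numeric or
#' non-finite values are dropped with a logged warning as long as their
#' fraction stays below `dialect$max_bad_frac`; above it the file is rejected
#' naming the offending lines.
#'
#' @param path Path to the text file.
#' @param dialect A list as produced by [imu_dialect()]: `delim`, integer
#'   column indices `cols = c(ml=, ap=, vert=)`, `skip` header lines,
#'   `unit` multiplier to m s^-2, `max_bad_frac`.
#' @param fs_in Acquisition rate, Hz.
#' @param subject_id,group,condition,visit Trial metadata (see
#'   [sway_recording()]).
#' @return A [sway_recording()].
#' @export
read_imu_text <- function(path, dialect = imu_dialect(), fs_in = 500,
                          subject_id = NA_character_, group = NA_character_,
                          condition = NA_character_, visit = NA_integer_) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  if (dialect$skip > 0) lines <- lines[-seq_len(min(dialect$skip, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(sprintf("no samples in %s", path))
  fields <- strsplit(lines, dialect$delim, fixed = TRUE)
  need <- max(unlist(dialect$cols))
  mat <- vapply(fields, function(f) {
    if (length(f) < need) return(rep(NA_real_, 3))
    suppressWarnings(as.numeric(f[unlist(dialect$cols)]))
  }, numeric(3))
  mat <- t(mat)
  bad <- !complete.cases(mat) | !is.finite(rowSums(mat))
  if (any(bad)) {
    frac <- mean(bad)
    if (frac > dialect$max_bad_frac) {
      abort(sprintf(
        "%s: %d malformed rows (%.1f%% > %.1f%% tolerated); first lines: %s",
        path, sum(bad), 100 * frac, 100 * dialect$max_bad_frac,
        paste(head(which(bad) + dialect$skip, 5), collapse = ", ")
      ))
    }
    sway_log("WARN", sprintf("%s: dropped %d malformed row(s)", path, sum(bad)))
    mat <- mat[!bad, , drop = FALSE]
  }
  if (!nrow(mat)) abort(sprintf("no samples in %s", path))
  acc <- tibble(
    ml = mat[, 1] * dialect$unit,
    ap = mat[, 2] * dialect$unit,
    vert = mat[, 3] * dialect$unit
  )
  sway_recording(acc, fs_in = fs_in, subject_id = subject_id, group = group,
                 condition = condition, visit = visit)
}

#' Declare the text dialect of an IMU export
#'
#' @param delim Field delimiter (tab by default).
#' @param cols Named integer vector mapping `ml`, `ap`, `vert` to column
#'   positions in the file.
#' @param skip Number of header lines to skip.
#' @param unit Multiplier converting file values to m s^-2.
#' @param max_bad_frac Maximum tolerated fraction of malformed rows.
#' @return A dialect list for [read_imu_text()].
#' @export
imu_dialect <- function(delim = "\t", cols = c(ml = 1L, ap = 2L, vert = 3L),
                        skip = 0L, unit = 1, max_bad_frac = 0.01) {
  stopifnot(all(c("ml", "ap", "vert") %in% names(cols)))
  list(delim = delim, cols = as.list(cols[c("ml", "ap", "vert")]),
       skip = skip, unit = unit, max_bad_frac = max_bad_frac)
}

#' Write an IMU trial in the package's text dialect
#'
#' Inverse of [read_imu_text()] under the same dialect; used by the cohort
#' simulator so generated fixtures exercise the real reader.
#'
#' @param rec A [sway_recording()].
#' @param path Output path.
#' @param dialect Dialect list (only `delim` and `unit` are used; axes are
#'   written in ml, ap, vert order).
#' @return `path`, invisibly.
#' @export
write_imu_text <- function(rec, path, dialect = imu_dialect()) {
  mat <- cbind(rec$acc$ml, rec$acc$ap, rec$acc$vert) / dialect$unit
  readr::write_lines(
    paste(format(mat[, 1], trim = TRUE, digits = 10),
          format(mat[, 2], trim = TRUE, digits = 10),
          format(mat[, 3], trim = TRUE, digits = 10),
          sep = dialect$delim),
    path
  )
  invisible(path)
}

study_table_cols <- c("subject", "group", "condition", "visit", "axis",
                      "measure", "value", "units")

#' Write or read a long-format measure table
#'
#' The study table is the long per-trial measure format used throughout the
#' package: one row per (subject, group, condition, visit, axis, measure).
#' `write_measures()` writes it as CSV with a fixed header; missing values are
#' written as literal `NA`. The pair round-trips losslessly.
#'
#' @param table A data frame with columns `subject`, `group`, `condition`,
#'   `visit`, `axis`, `measure`, `value` and optionally `units`.
#' @param path CSV path.
#' @return `write_measures()` returns `path` invisibly; `read_measures()`
#'   returns a tibble with the fixed column set.
#' @export
write_measures <- function(table, path) {
  if (!nrow(table)) abort("refusing to write an empty measure table")
  table <- as_tibble(table)
  if (!"units" %in% names(table)) table$units <- NA_character_
  missing_cols <- setdiff(setdiff(study_table_cols, "units"), names(table))
  if (length(missing_cols)) {
    abort(paste0("measure table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(table[study_table_cols], path, na = "NA")
  invisible(path)
}

#' @rdname write_measures
#' @export
read_measures <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_csv(
    path,
    col_types = readr::cols(
      subject = readr::col_character(), group = readr::col_character(),
      condition = readr::col_character(), visit = readr::col_integer(),
      axis = readr::col_character(), measure = readr::col_character(),
      value = readr::col_double(), units = readr::col_character()
    )
  )
}
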