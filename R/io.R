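#' File dialect for bracelet-style recordings
#'
#' Recordings are stored as plain comma-separated text with two header
#' lines: the column names `t,ax,ay,az,gx,gy,gz` followed by a mandatory
#' units row `s,G,G,G,dps,dps,dps`. The units row exists to prevent silent
#' G vs m/s^2 confusion. Column order is fixed; readers reject any
#' deviation rather than repairing it. Values are written at full
#' round-trip precision, so write -> read reproduces every sample exactly.
#'
#' @name recording_dialect
NULL

DIALECT_NAMES <- c("t", CHANNELS)
DIALECT_UNITS <- c("s", "G", "G", "G", "dps", "dps", "dps")

#' Write / read a recording CSV
#'
#' `write_recording()` serializes a recording in the [recording_dialect]
#' (two header lines, then one row per sample). `read_recording()` parses
#' such a file, validates the dialect strictly (column order, units row,
#' numeric cells, strictly increasing timestamps) and infers the sampling
#' rate from the median timestamp step. Subject metadata is not part of the
#' on-disk dialect; pass it to `read_recording()` (cohort-level readers take
#' it from the manifest).
#'
#' @param rec A `pd_recording`.
#' @param path File path.
#' @param subject_id,class_label,task Metadata attached to the returned
#'   recording.
#' @return `read_recording()` returns a `pd_recording`.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "pd_recording"))
    abort_invalid("`rec` must be a `pd_recording`.")
  writeLines(c(paste(DIALECT_NAMES, collapse = ","),
               paste(DIALECT_UNITS, collapse = ",")), path)
  body <- tibble::as_tibble(rec)[DIALECT_NAMES]
  readr::write_csv(body, path, col_names = FALSE, append = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, subject_id = "unknown",
                           class_label = "healthy", task = "rest") {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  hdr <- readLines(path, n = 2)
  if (length(hdr) < 2)
    abort_format(sprintf("%s: fewer than two header lines.", path))
  if (!identical(trimws(strsplit(hdr[1], ",")[[1]]), DIALECT_NAMES))
    abort_format(sprintf(
      "%s: line 1 must name the columns '%s' in this exact order.",
      path, paste(DIALECT_NAMES, collapse = ",")))
  if (!identical(trimws(strsplit(hdr[2], ",")[[1]]), DIALECT_UNITS))
    abort_format(sprintf("%s: line 2 must be the units row '%s'.",
                         path, paste(DIALECT_UNITS, collapse = ",")))
  df <- tryCatch(
    tibble::as_tibble(utils::read.csv(path, skip = 2, header = FALSE,
                                      col.names = DIALECT_NAMES,
                                      colClasses = "numeric",
                                      check.names = FALSE)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(df)) locate_bad_cell(path, skip = 2, n_cols = 7)
  if (nrow(df) < 2)
    abort_format(sprintf("%s: fewer than two samples.", path))
  dt <- diff(df$t)
  if (any(dt <= 0))
    abort_format(sprintf(
      "%s: timestamps not strictly increasing at line %d.",
      path, which(dt <= 0)[1] + 3L))
  fs <- 1 / median(dt)
  new_recording(df, subject_id = subject_id, class_label = class_label,
                task = task, sampling_rate_hz = fs)
}

#' Write / read a cohort directory
#'
#' One dialect CSV per recording plus a `manifest.csv` carrying the
#' subject/class/task metadata, so a cohort round-trips losslessly.
#'
#' @param cohort A `pd_cohort`.
#' @param dir Directory (created if missing).
#' @return `read_cohort()` returns a `pd_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%s.csv", cohort$subject_id, cohort$task)
  purrr::walk2(cohort$data, files,
               function(rec, f) write_recording(rec, file.path(dir, f)))
  manifest <- tibble::tibble(subject_id = cohort$subject_id,
                             class_label = cohort$class_label,
                             task = cohort$task, file = files)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath))
    abort_format(sprintf("no manifest.csv in %s", dir))
  manifest <- readr::read_csv(mpath, col_types = "cccc", progress = FALSE)
  need <- c("subject_id", "class_label", "task", "file")
  if (!identical(names(manifest), need))
    abort_format("manifest.csv must have columns subject_id, class_label, task, file.")
  recs <- purrr::pmap(manifest, function(subject_id, class_label, task, file) {
    read_recording(file.path(dir, file), subject_id = subject_id,
                   class_label = class_label, task = task)
  })
  out <- manifest[c("subject_id", "class_label", "task")]
  out$data <- recs
  class(out) <- c("pd_cohort", class(out))
  out
}

#' Write / read a feature table CSV
#'
#' Plain CSV with `subject_id`, `class_label`, then one column per named
#' feature. Duplicate feature names and missing label columns are format
#' errors, not repairs.
#'
#' @param table A feature table (tibble).
#' @param path File path.
#' @return `read_feature_table()` returns the feature table tibble.
#' @export
write_feature_table <- function(table, path) {
  check_feature_table(table)
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  nm <- trimws(strsplit(readLines(path, n = 1), ",")[[1]])
  if (length(nm) < 3 || nm[1] != "subject_id" || nm[2] != "class_label")
    abort_format(sprintf(
      "%s: first two columns must be subject_id, class_label.", path))
  if (anyDuplicated(nm))
    abort_format(sprintf("%s: duplicate feature name '%s'.",
                         path, nm[duplicated(nm)][1]))
  tbl <- tryCatch(
    tibble::as_tibble(utils::read.csv(
      path, colClasses = c("character", "character",
                           rep("numeric", length(nm) - 2)),
      check.names = FALSE)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tbl))
    locate_bad_cell(path, skip = 1, n_cols = length(nm), char_cols = 2)
  check_feature_table(tbl)
  tbl
}

# Diagnostic pass after a failed strict numeric parse: name the first
# malformed line (wrong field count or non-numeric cell) and abort.
locate_bad_cell <- function(path, skip, n_cols, char_cols = 0) {
  lines <- readLines(path)
  for (i in seq_along(lines)[-seq_len(skip)]) {
    fields <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(fields) != n_cols)
      abort_format(sprintf("%s: line %d has %d fields, expected %d.",
                           path, i, length(fields), n_cols))
    num <- fields[(char_cols + 1):n_cols]
    bad <- which(is.na(suppressWarnings(as.numeric(num))))
    if (length(bad) > 0)
      abort_format(sprintf("%s: non-numeric cell at line %d, column %d.",
                           path, i, char_cols + bad[1]))
  }
  abort_format(sprintf("%s: malformed file.", path))
}

check_feature_table <- function(table) {
  if (!is.data.frame(table) || ncol(table) < 3 ||
      names(table)[1] != "subject_id" || names(table)[2] != "class_label")
    abort_format("feature table must start with subject_id, class_label columns.")
  if (anyDuplicated(names(table)))
    abort_format(sprintf("duplicate feature name '%s'.",
                         names(table)[duplicated(names(table))][1]))
  bad <- setdiff(unique(table$class_label), CLASS_LEVELS)
  if (length(bad) > 0)
    abort_format(sprintf("unknown class label '%s'.", bad[1]))
  invisible(table)
}

feature_names <- function(table) setdiff(names(table), c("subject_id", "class_label"))
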