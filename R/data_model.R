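#' Single-axis tremor recording
#'
#' One 20-second, single-axis accelerometer recording with full provenance:
#' patient, diagnostic group, visit, hand, task, trial and axis. Amplitudes
#' are in arbitrary calibrated units; the constant calibration offset is
#' removed later by demeaning.
#'
#' @param samples numeric vector of acceleration samples.
#' @param fs sampling rate in Hz (clinically 1500; 100 after preprocessing).
#' @param patient_id patient identifier.
#' @param group "PD", "ET" or "unknown" (for inference-only data).
#' @param visit visit number (>= 1).
#' @param hand "left" or "right".
#' @param task canonical task name.
#' @param trial trial number in 1..3.
#' @param axis "x", "y" or "z".
#' @return an object of class `tremor_signal`.
#' @export
tremor_signal <- function(samples, fs, patient_id, group = "unknown",
                          visit = 1L, hand = "right", task = "Rest1",
                          trial = 1L, axis = "x") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("empty signal")
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("signal contains non-finite samples")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  visit <- as.integer(visit)
  if (is.na(visit) || visit < 1L) stop("visit must be >= 1")
  trial <- as.integer(trial)
  if (is.na(trial) || trial < 1L || trial > 3L) stop("trial must be in 1..3")
  structure(
    list(samples = samples, fs = as.numeric(fs),
         patient_id = as.character(patient_id),
         group = canonical_group(group), visit = visit,
         hand = canonical_hand(hand), task = canonical_task(task),
         trial = trial, axis = canonical_axis(axis)),
    class = "tremor_signal")
}

#' @export
print.tremor_signal <- function(x, ...) {
  cat(sprintf(
    "<tremor_signal> %s %s visit %d %s hand, %s trial %d axis %s: %d samples @ %g Hz\n",
    x$patient_id, x$group, x$visit, x$hand, x$task, x$trial, x$axis,
    length(x$samples), x$fs))
  invisible(x)
}

signal_key <- function(patient_id, visit, hand, task, trial, axis) {
  paste(patient_id, visit, hand, task, trial, axis, sep = "|")
}

assessment_key <- function(patient_id, visit, hand) {
  paste(patient_id, visit, hand, sep = "|")
}

manifest_columns <- function() {
  c("patient_id", "group", "visit", "hand", "task", "trial", "axis", "fs",
    "file_path")
}

validate_manifest_frame <- function(df, check_files = TRUE) {
  missing <- setdiff(manifest_columns(), names(df))
  if (length(missing) > 0L) {
    stop(sprintf("manifest schema error: missing column(s) %s",
                 paste(missing, collapse = ", ")))
  }
  df <- df[manifest_columns()]
  df$patient_id <- as.character(df$patient_id)
  df$group <- canonical_group(df$group)
  df$visit <- as.integer(df$visit)
  df$hand <- canonical_hand(df$hand)
  df$task <- canonical_task(df$task)
  df$trial <- as.integer(df$trial)
  df$axis <- canonical_axis(df$axis)
  df$fs <- as.numeric(df$fs)
  df$file_path <- as.character(df$file_path)
  if (any(is.na(df$visit) | df$visit < 1L)) stop("visit must be >= 1")
  if (any(is.na(df$trial) | df$trial < 1L | df$trial > 3L)) {
    stop("trial must be in 1..3")
  }
  if (any(is.na(df$fs) | df$fs <= 0)) stop("fs must be > 0")
  key <- signal_key(df$patient_id, df$visit, df$hand, df$task, df$trial,
                    df$axis)
  if (anyDuplicated(key)) {
    stop(sprintf("manifest integrity error: duplicate entries (%s)",
                 key[duplicated(key)][1L]))
  }
  if (check_files) {
    have <- !is.na(df$file_path) & nzchar(df$file_path)
    if (any(!have)) stop("manifest integrity error: missing file paths")
    absent <- !file.exists(df$file_path)
    if (any(absent)) {
      stop(sprintf("manifest I/O error: file not found: %s",
                   df$file_path[absent][1L]))
    }
  }
  df$excluded <- task_excluded(df$task)
  rownames(df) <- NULL
  df
}

#' Load a cohort manifest
#'
#' The manifest is a comma-separated file with a header row and columns
#' `patient_id,group,visit,hand,task,trial,axis,fs,file_path`. Task, axis,
#' hand and group strings are matched case-insensitively. Finger-to-nose
#' rows load but are flagged `excluded`.
#'
#' @param path path to the CSV manifest.
#' @param check_files verify that every referenced signal file exists.
#' @return a `cohort_manifest`: a data frame of validated entries with an
#'   `excluded` flag column.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop(sprintf("manifest I/O error: %s", path))
  if (file.size(path) == 0L) {
    stop("manifest schema error: empty file (no header)")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- validate_manifest_frame(df, check_files = check_files)
  # resolve relative signal paths against the manifest's directory
  structure(df, class = c("cohort_manifest", class(df)),
            provenance = normalizePath(path))
}

#' Write a cohort manifest
#'
#' @param manifest a `cohort_manifest` or conforming data frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)[manifest_columns()]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one signal file
#'
#' Signal files are plain text, one numeric sample per line, no header.
#' The sample count must match `fs` x 20 s within one sample.
#'
#' @param entry one manifest row (list or single-row data frame).
#' @param duration_s nominal recording duration (20 s clinically).
#' @return a [tremor_signal()].
#' @export
read_signal <- function(entry, duration_s = 20) {
  entry <- as.list(entry)
  if (!file.exists(entry$file_path)) {
    stop(sprintf("signal I/O error: %s", entry$file_path))
  }
  raw <- readLines(entry$file_path)
  raw <- raw[nzchar(trimws(raw))]
  samples <- suppressWarnings(as.numeric(raw))
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop(sprintf("signal parse error: non-numeric row in %s",
                 entry$file_path))
  }
  expected <- round(duration_s * entry$fs)
  if (abs(length(samples) - expected) > 1L) {
    stop(sprintf(
      "signal integrity error: %s has %d samples, expected %d (fs=%g)",
      entry$file_path, length(samples), expected, entry$fs))
  }
  tremor_signal(samples, fs = entry$fs, patient_id = entry$patient_id,
                group = entry$group, visit = entry$visit, hand = entry$hand,
                task = entry$task, trial = entry$trial, axis = entry$axis)
}

write_signal_file <- function(samples, path) {
  writeLines(formatC(samples, format = "g", digits = 17), path)
  invisible(path)
}

#' In-memory tremor cohort
#'
#' A cohort bundles a manifest with the signal samples keyed by
#' (patient, visit, hand, task, trial, axis), so pipelines can run without
#' touching the filesystem. [load_cohort()] materialises a cohort from a
#' manifest on disk; [simulate_cohort()] generates one synthetically.
#'
#' @param manifest validated manifest data frame.
#' @param signals named list of numeric sample vectors keyed like the
#'   manifest rows.
#' @return an object of class `tremor_cohort`.
#' @export
tremor_cohort <- function(manifest, signals) {
  key <- signal_key(manifest$patient_id, manifest$visit, manifest$hand,
                    manifest$task, manifest$trial, manifest$axis)
  if (!all(key %in% names(signals))) {
    stop("cohort integrity error: manifest entry without samples")
  }
  structure(list(manifest = manifest, signals = signals),
            class = "tremor_cohort")
}

#' @export
print.tremor_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<tremor_cohort> %d signals, %d patients (%d PD / %d ET), %d excluded task rows\n",
    nrow(m), length(unique(m$patient_id)),
    length(unique(m$patient_id[m$group == "PD"])),
    length(unique(m$patient_id[m$group == "ET"])), sum(m$excluded)))
  invisible(x)
}

#' @rdname tremor_cohort
#' @param manifest a `cohort_manifest` loaded with [load_manifest()].
#' @param duration_s nominal recording duration in seconds.
#' @export
load_cohort <- function(manifest, duration_s = 20) {
  sigs <- vector("list", nrow(manifest))
  key <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    entry <- as.list(manifest[i, ])
    s <- read_signal(entry, duration_s = duration_s)
    key[i] <- signal_key(entry$patient_id, entry$visit, entry$hand,
                         entry$task, entry$trial, entry$axis)
    sigs[[i]] <- s$samples
  }
  names(sigs) <- key
  tremor_cohort(as.data.frame(manifest), sigs)
}

cohort_signal <- function(cohort, entry) {
  key <- signal_key(entry$patient_id, entry$visit, entry$hand, entry$task,
                    entry$trial, entry$axis)
  tremor_signal(cohort$signals[[key]], fs = entry$fs,
                patient_id = entry$patient_id, group = entry$group,
                visit = entry$visit, hand = entry$hand, task = entry$task,
                trial = entry$trial, axis = entry$axis)
}

#' Assemble complete tremor assessments
#'
#' Groups cohort entries by (patient, visit, hand), drops the excluded
#' finger-to-nose rows and returns only complete assessments: exactly 54
#' signals, 6 static tasks x 3 trials x 3 axes. Incomplete groups are not an
#' error; they are reported in the `incomplete` attribute.
#'
#' @param cohort a `tremor_cohort`.
#' @return list of `tremor_assessment` objects, each holding 54
#'   [tremor_signal()]s keyed canonically, with attribute `incomplete`
#'   (data frame of skipped groups and their signal counts).
#' @export
assemble_assessments <- function(cohort) {
  stopifnot(inherits(cohort, "tremor_cohort"))
  m <- cohort$manifest[!cohort$manifest$excluded, , drop = FALSE]
  akey <- assessment_key(m$patient_id, m$visit, m$hand)
  out <- list()
  skipped <- list()
  for (k in unique(akey)) {
    rows <- m[akey == k, , drop = FALSE]
    if (length(unique(rows$group)) != 1L) {
      stop(sprintf("assessment %s mixes group labels", k))
    }
    if (nrow(rows) != 54L) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(assessment = k, n_signals = nrow(rows))
      next
    }
    sigs <- vector("list", 54L)
    for (i in seq_len(54L)) {
      entry <- as.list(rows[i, ])
      sigs[[feature_index(entry$trial, entry$task, entry$axis) + 1L]] <-
        cohort_signal(cohort, entry)
    }
    if (any(vapply(sigs, is.null, logical(1)))) {
      # duplicates collapse onto one slot; cannot happen for a validated
      # manifest, but guard against hand-built cohorts
      skipped[[length(skipped) + 1L]] <-
        data.frame(assessment = k, n_signals = nrow(rows))
      next
    }
    names(sigs) <- feature_order()$label
    out[[length(out) + 1L]] <- structure(
      list(patient_id = rows$patient_id[1L], group = rows$group[1L],
           visit = rows$visit[1L], hand = rows$hand[1L], signals = sigs),
      class = "tremor_assessment")
  }
  incomplete <- if (length(skipped) > 0L) do.call(rbind, skipped) else
    data.frame(assessment = character(0), n_signals = integer(0))
  structure(out, incomplete = incomplete)
}

#' @export
print.tremor_assessment <- function(x, ...) {
  cat(sprintf("<tremor_assessment> %s (%s) visit %d %s hand: %d signals\n",
              x$patient_id, x$group, x$visit, x$hand, length(x$signals)))
  invisible(x)
}
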