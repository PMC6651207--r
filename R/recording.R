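#' EEG recordings
#'
#' A recording holds one subject-task session: a channels x time matrix at
#' a fixed sampling rate, the montage labels, and the task script that
#' timestamps its sub-tasks.
#'
#' @param data Numeric matrix, channels in rows (montage order), samples in
#'   columns.
#' @param fs Sampling rate in samples/s (128 for the study headset).
#' @param subject_id Subject identifier.
#' @param task Task label (`"KATA"` or `"CPDnA"` for the presets).
#' @param channel_names Ordered channel labels; defaults to [aes_montage()].
#' @param script A [task_script()] whose total duration matches
#'   `ncol(data) / fs`.
#' @param seed Optional integer recording the simulation seed (metadata).
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs, subject_id, task,
                          channel_names = aes_montage(),
                          script = NULL, seed = NULL) {
  stopifnot(is.matrix(data), fs > 0)
  if (nrow(data) != length(channel_names)) {
    stop(sprintf("data has %d rows but %d channel names",
                 nrow(data), length(channel_names)))
  }
  if (!is.null(script)) {
    expected <- round(fs * script$total_duration)
    if (ncol(data) != expected) {
      stop(sprintf("data has %d samples; script implies %d at fs=%g",
                   ncol(data), expected, fs))
    }
  }
  rownames(data) <- channel_names
  structure(
    list(subject_id = subject_id, task = task, fs = fs, data = data,
         channel_names = channel_names, script = script, seed = seed),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: subject %s, task %s\n", x$subject_id, x$task))
  cat(sprintf("  %d channels x %d samples (%.1f s at %g samples/s)\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$fs, x$fs))
  cat(sprintf("  signal range [%.3g, %.3g]\n", min(x$data), max(x$data)))
  invisible(x)
}

duration_s <- function(recording) ncol(recording$data) / recording$fs

#' Extract the samples of one sub-task interval
#'
#' Returns the recording restricted to the interval of the named sub-task
#' (e.g. the 250-s `"KATA-III"` or `"Plan"` analysis window).
#'
#' @param recording An `eeg_recording` with a task script.
#' @param subtask Sub-task label present in the script.
#' @return An `eeg_recording` covering only that interval (script reduced
#'   to the single sub-task).
#' @export
subtask_window <- function(recording, subtask) {
  sc <- recording$script
  if (is.null(sc)) stop("recording has no task script")
  i <- match(subtask, sc$labels)
  if (is.na(i)) {
    stop(sprintf("sub-task '%s' not in script (has: %s)", subtask,
                 paste(sc$labels, collapse = ", ")))
  }
  ends <- cumsum(sc$durations)
  from <- round(recording$fs * c(0, ends)[i]) + 1L
  to <- round(recording$fs * ends[i])
  out <- recording
  out$data <- recording$data[, from:to, drop = FALSE]
  out$script <- task_script(recording$task, subtask, sc$durations[i])
  out
}

#' Write a simulated cohort to disk
#'
#' One CSV per subject-task (first column `time` in seconds, then one
#' column per channel, header = montage labels) plus a JSON manifest with
#' subject, task, sampling rate, seed and script per entry.
#'
#' @param recordings List of `eeg_recording`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame (with file paths).
#' @export
write_cohort <- function(recordings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(recordings, function(r) {
    file <- file.path(dir, sprintf("%s_%s.csv", r$subject_id, r$task))
    tt <- (seq_len(ncol(r$data)) - 1) / r$fs
    df <- data.frame(time = tt, t(r$data), check.names = FALSE)
    utils::write.csv(df, file, row.names = FALSE)
    list(file = basename(file), subject_id = r$subject_id, task = r$task,
         fs = r$fs, seed = r$seed,
         script = list(labels = r$script$labels,
                       durations = r$script$durations))
  })
  jsonlite::write_json(entries, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(do.call(rbind, lapply(entries, function(e) {
    data.frame(file = e$file, subject_id = e$subject_id, task = e$task,
               fs = e$fs)
  })))
}

#' Read a recording from disk
#'
#' Reads the CSV dialect written by [write_cohort()]: first column time in
#' seconds, one column per channel. Columns may appear in any order and
#' are reordered to the montage; missing montage channels are an error.
#' The sampling rate is inferred from the time column; if `expected_fs` is
#' given, a mismatch is a hard error (no silent resampling).
#'
#' @param path Path to the file.
#' @param format `"CSV"` (the supported on-disk dialect). `"EDF"` is
#'   recognized but not implemented and errors.
#' @param subject_id,task Metadata; inferred from a `subject_task.csv`
#'   filename when omitted.
#' @param script Task script; defaults to the preset for `task` when the
#'   duration matches.
#' @param expected_fs Optional sampling-rate check.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("CSV", "EDF"), subject_id = NULL,
                           task = NULL, script = NULL, expected_fs = NULL) {
  format <- match.arg(format)
  if (format == "EDF") {
    stop("EDF input is not supported; write cohorts as CSV (see write_cohort)")
  }
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("CSV must have a 'time' first column")
  missing <- setdiff(aes_montage(), names(df))
  if (length(missing) > 0) {
    stop("missing montage channels: ", paste(missing, collapse = ", "))
  }
  fs <- 1 / stats::median(diff(df$time))
  fs <- round(fs, 6)
  if (!is.null(expected_fs) && abs(fs - expected_fs) > 1e-6) {
    stop(sprintf(
      "sampling rate %g does not match expected %g; refusing to resample",
      fs, expected_fs))
  }
  base <- sub("\\.csv$", "", basename(path))
  if (is.null(subject_id) || is.null(task)) {
    parts <- strsplit(base, "_", fixed = TRUE)[[1]]
    if (length(parts) >= 2) {
      if (is.null(subject_id)) subject_id <- parts[1]
      if (is.null(task)) task <- paste(parts[-1], collapse = "_")
    }
  }
  data <- t(as.matrix(df[, aes_montage(), drop = FALSE]))
  if (is.null(script) && !is.null(task) && task %in% c("KATA", "CPDnA")) {
    sc <- script_for_task(task)
    if (round(fs * sc$total_duration) == ncol(data)) script <- sc
  }
  eeg_recording(data, fs = fs, subject_id = subject_id %||% base,
                task = task %||% "unknown", script = script)
}
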