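#' Preprocessing configuration
#'
#' The preprocessing chain applies, in order: a causal high-pass filter
#' (default 1 Hz cut-off) to remove DC offset and slow drift, a causal
#' low-pass filter (default 50 Hz) to remove high-frequency noise, and a
#' per-channel min-max normalization to \[0, 1\]. Both filters are
#' forward-only Butterworth IIR filters (default order 5): sample t of the
#' output depends only on input samples at or before t, so event timing is
#' never smeared backwards.
#'
#' @param highpass_cutoff High-pass cut-off in Hz.
#' @param lowpass_cutoff Low-pass cut-off in Hz.
#' @param filter_order Butterworth order for both filters.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(highpass_cutoff = 1, lowpass_cutoff = 50,
                              filter_order = 5) {
  stopifnot(highpass_cutoff > 0, lowpass_cutoff > highpass_cutoff,
            filter_order >= 1)
  structure(list(highpass_cutoff = highpass_cutoff,
                 lowpass_cutoff = lowpass_cutoff,
                 filter_order = as.integer(filter_order),
                 causal = TRUE),
            class = "preprocess_config")
}

#' Apply the causal band filters to a recording
#'
#' @param recording An `eeg_recording` at least 2 s long (filter warm-up).
#' @param config A [preprocess_config()].
#' @return The filtered recording.
#' @export
apply_filters <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (config$lowpass_cutoff >= fs / 2) {
    stop(sprintf("low-pass cutoff %g Hz is at or above Nyquist (%g Hz)",
                 config$lowpass_cutoff, fs / 2))
  }
  if (duration_s(recording) < 2) {
    stop("recording shorter than 2 s; too short for filter warm-up")
  }
  hp <- signal::butter(config$filter_order,
                       config$highpass_cutoff / (fs / 2), type = "high")
  lp <- signal::butter(config$filter_order,
                       config$lowpass_cutoff / (fs / 2), type = "low")
  out <- recording
  out$data <- t(apply(recording$data, 1, function(x) {
    signal::filter(lp, signal::filter(hp, x))
  }))
  rownames(out$data) <- recording$channel_names
  out
}

#' Normalize each channel to the range \[0, 1\]
#'
#' Per-channel min-max scaling over the whole recording. This is an affine
#' map per channel, so rank order and inter-channel correlations are
#' preserved while absolute amplitude (subject-identifying information) is
#' erased.
#'
#' @param recording An `eeg_recording`.
#' @return The recording with every channel spanning exactly \[0, 1\].
#' @export
normalize01 <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  rng <- apply(recording$data, 1, range)
  span <- rng[2, ] - rng[1, ]
  if (any(span == 0)) {
    stop("constant channel(s), cannot normalize: ",
         paste(recording$channel_names[span == 0], collapse = ", "))
  }
  out <- recording
  out$data <- (recording$data - rng[1, ]) / span
  out$normalized <- TRUE
  out
}

#' Run the full preprocessing chain
#'
#' Filter (high-pass then low-pass, causal) followed by per-channel
#' normalization to \[0, 1\], in that order.
#'
#' @inheritParams apply_filters
#' @return The preprocessed recording.
#' @export
preprocess <- function(recording, config = preprocess_config()) {
  pre_rng <- range(recording$data)
  out <- normalize01(apply_filters(recording, config))
  message(sprintf(
    "preprocess: %s/%s range [%.3g, %.3g] -> [%g, %g]",
    recording$subject_id, recording$task, pre_rng[1], pre_rng[2],
    min(out$data), max(out$data)))
  out
}

#' Split a recording into fixed-length segments
#'
#' Cuts the recording into consecutive non-overlapping windows (1 s by
#' default), dropping any trailing partial window. Each segment carries
#' the sub-task label of the script interval containing its start sample.
#'
#' @param recording A preprocessed `eeg_recording`.
#' @param window_s Window length in seconds; `window_s * fs` must be a
#'   whole number of samples.
#' @return List of `eeg_segment` objects (possibly empty), each a list
#'   with `subject_id`, `task`, `subtask`, `index`, `fs` and a
#'   channels x samples `data` matrix.
#' @export
segment_recording <- function(recording, window_s = 1) {
  stopifnot(inherits(recording, "eeg_recording"), window_s > 0)
  w <- recording$fs * window_s
  if (abs(w - round(w)) > 1e-9) {
    stop("window_s * fs must be an integer number of samples")
  }
  w <- as.integer(round(w))
  n_seg <- ncol(recording$data) %/% w
  if (n_seg == 0) return(list())
  lapply(seq_len(n_seg), function(i) {
    start <- (i - 1L) * w
    label <- if (is.null(recording$script)) NA_character_ else {
      subtask_at(recording$script, start / recording$fs)
    }
    structure(
      list(subject_id = recording$subject_id, task = recording$task,
           subtask = label, index = i, fs = recording$fs,
           data = recording$data[, (start + 1L):(start + w), drop = FALSE]),
      class = "eeg_segment")
  })
}
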