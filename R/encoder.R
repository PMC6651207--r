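#' Encode a 1-s segment as an RGB image
#'
#' The multichannel method: channels are grouped into triplets
#' ([group_channels()]), each triplet becomes one pixel row, and its three
#' channels map to the red, green and blue planes. Column t holds sample
#' t, so a 1-s segment at 128 samples/s becomes a width-128 image; the
#' 14-channel montage gives 5 rows (the last triplet padded with a null
#' channel that encodes 0). Signal values, already normalized to \[0, 1\],
#' are quantized to 8 bits as `floor(v * 255 + 0.5)` (round half up).
#'
#' @param segment An `eeg_segment` with values in \[0, 1\].
#' @return An `encoded_image`: list with integer `pixels`
#'   (rows x width x 3, values 0-255), `label` (task), `subject_id`,
#'   `subtask` and `segment_index`.
#' @export
encode_segment <- function(segment) {
  stopifnot(inherits(segment, "eeg_segment"))
  x <- segment$data
  if (any(x < 0) || any(x > 1)) {
    stop("segment values outside [0, 1]; normalize the recording first")
  }
  triplets <- group_channels(rownames(x))
  h <- length(triplets)
  w <- ncol(x)
  px <- array(0L, dim = c(h, w, 3))
  for (r in seq_len(h)) {
    for (p in 1:3) {
      ch <- triplets[[r]][p]
      if (!is.na(ch)) {
        px[r, , p] <- as.integer(floor(x[ch, ] * 255 + 0.5))
      }
    }
  }
  structure(
    list(pixels = px, label = segment$task, subject_id = segment$subject_id,
         subtask = segment$subtask, segment_index = segment$index,
         fs = segment$fs),
    class = "encoded_image")
}

#' Decode an RGB image back to a segment
#'
#' Inverse of [encode_segment()] up to 8-bit quantization: each recovered
#' value is within 1/255 of the original. Used as the round-trip oracle
#' and to reconstruct signals from stored PNGs.
#'
#' @param image An `encoded_image`, or a plain rows x width x 3 array with
#'   values either 0-255 integers or \[0, 1\] reals (as returned by
#'   [png::readPNG()]).
#' @param montage Channel labels the image encodes; default
#'   [aes_montage()].
#' @return An `eeg_segment` with the recovered channels x samples matrix.
#' @export
decode_image <- function(image, montage = aes_montage()) {
  meta <- list(subject_id = NA, task = NA, subtask = NA, index = NA, fs = NA)
  if (inherits(image, "encoded_image")) {
    meta <- list(subject_id = image$subject_id, task = image$label,
                 subtask = image$subtask, index = image$segment_index,
                 fs = image$fs)
    px <- image$pixels
  } else {
    px <- image
  }
  stopifnot(length(dim(px)) == 3, dim(px)[3] == 3)
  triplets <- group_channels(montage)
  if (dim(px)[1] != length(triplets)) {
    stop(sprintf("image has %d rows; montage of %d channels needs %d",
                 dim(px)[1], length(montage), length(triplets)))
  }
  if (max(px) > 1) px <- px / 255
  w <- dim(px)[2]
  data <- matrix(0, length(montage), w, dimnames = list(montage, NULL))
  for (r in seq_along(triplets)) {
    for (p in 1:3) {
      ch <- triplets[[r]][p]
      if (!is.na(ch)) data[ch, ] <- px[r, , p]
    }
  }
  structure(
    list(subject_id = meta$subject_id, task = meta$task,
         subtask = meta$subtask, index = meta$index,
         fs = if (is.na(meta$fs)) w else meta$fs, data = data),
    class = "eeg_segment")
}

#' Build the labeled image dataset from a cohort
#'
#' Preprocessed recordings are segmented into 1-s windows; every segment
#' whose sub-task label is in `analysis_subtasks` (by default the two
#' 250-s analysis windows, KATA-III and Plan) is encoded and written as
#' one small PNG. For the 24-subject study design this yields
#' 24 x 2 x 250 = 12,000 images, 6,000 per class.
#'
#' @param recordings List of preprocessed `eeg_recording` objects.
#' @param dir Output directory for PNGs and `manifest.csv`.
#' @param analysis_subtasks Sub-task labels to keep.
#' @return The manifest data.frame (`path`, `subject_id`, `task`,
#'   `segment_index`), with a `class_counts` attribute, invisibly written
#'   to `dir/manifest.csv`.
#' @export
build_image_dataset <- function(recordings, dir,
                                analysis_subtasks = c("KATA-III", "Plan")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (rec in recordings) {
    if (is.null(rec$normalized) || !isTRUE(rec$normalized)) {
      stop("recordings must be preprocessed (normalized to [0,1]) first")
    }
    segs <- segment_recording(rec)
    segs <- Filter(function(s) s$subtask %in% analysis_subtasks, segs)
    for (s in segs) {
      img <- encode_segment(s)
      fname <- sprintf("%s_%s_%04d.png", s$subject_id, s$task, s$index)
      png::writePNG(img$pixels / 255, file.path(dir, fname))
      rows[[length(rows) + 1L]] <-
        data.frame(path = fname, subject_id = s$subject_id, task = s$task,
                   segment_index = s$index)
    }
  }
  if (length(rows) == 0) {
    stop("no segments matched analysis sub-tasks: ",
         paste(analysis_subtasks, collapse = ", "))
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "class_counts") <- table(manifest$task)
  attr(manifest, "dir") <- dir
  manifest
}

#' Read an image-dataset manifest written by [build_image_dataset()]
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @return The manifest data.frame with `class_counts` and `dir`
#'   attributes.
#' @export
read_image_manifest <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(path)
  attr(manifest, "class_counts") <- table(manifest$task)
  attr(manifest, "dir") <- dir
  manifest
}
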