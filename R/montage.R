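#' The 14-channel AES montage
#'
#' Channel labels of the 14-sensor headset montage, in the fixed listing
#' order used throughout the package (recordings, correlation matrices,
#' image rows). Naming follows the American Electroencephalographic
#' Society standard.
#'
#' @return Character vector of 14 channel labels.
#' @export
#' @examples
#' aes_montage()
aes_montage <- function() {
  c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
    "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
}

#' The six frontal sensors
#'
#' The frontal sensor group proxying prefrontal cortex in the coupling
#' hypotheses (P7/P8 proxy the left/right temporoparietal junction).
#'
#' @return Character vector of 6 channel labels.
#' @export
frontal_channels <- function() c("AF3", "F7", "F3", "AF4", "F4", "F8")

#' Group montage channels into RGB triplets
#'
#' Channels are grouped three at a time, in montage order, into the rows of
#' the encoded image; one triplet per pixel row, its members mapped to the
#' red, green and blue planes. A final incomplete triplet is padded with
#' `NA` (a null channel that encodes as black).
#'
#' @param channel_names Ordered character vector of channel labels.
#' @return List of character vectors of length 3 (padded with `NA`).
#' @export
#' @examples
#' group_channels(aes_montage())
group_channels <- function(channel_names) {
  if (length(channel_names) == 0) {
    stop("channel list is empty; nothing to group")
  }
  n_trip <- ceiling(length(channel_names) / 3L)
  padded <- c(channel_names, rep(NA_character_, n_trip * 3L - length(channel_names)))
  lapply(seq_len(n_trip), function(i) padded[(3L * i - 2L):(3L * i)])
}
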