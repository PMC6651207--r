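#' Shallow features of a 1-s segment
#'
#' Fixed-length descriptor merged with the learned convolutional features
#' at the soft sensor's fully connected layer: per channel, the mean,
#' standard deviation, and periodogram band power in the theta (4-8 Hz),
#' alpha (8-13 Hz) and beta (13-30 Hz) bands. For the 14-channel montage
#' this is 5 x 14 = 70 values. Deterministic.
#'
#' @param segment An `eeg_segment` with exactly `fs` samples (1 s).
#' @return Named numeric vector of length `5 * n_channels`.
#' @export
shallow_features <- function(segment) {
  stopifnot(inherits(segment, "eeg_segment"))
  x <- segment$data
  fs <- segment$fs
  n <- ncol(x)
  if (n != fs) {
    stop(sprintf("segment has %d samples; expected fs = %g (1 s)", n, fs))
  }
  bands <- list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
  half <- seq_len(n %/% 2)           # one-sided spectrum, DC excluded
  freqs <- half * fs / n
  out <- lapply(seq_len(nrow(x)), function(i) {
    v <- x[i, ]
    m <- mean(v)
    p <- Mod(stats::fft(v - m))^2 / n^2
    bp <- vapply(bands, function(b) {
      2 * sum(p[half + 1][freqs >= b[1] & freqs < b[2]])
    }, numeric(1))
    c(mean = m, sd = stats::sd(v), bp)
  })
  names(out) <- rownames(x)
  unlist(out)
}
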