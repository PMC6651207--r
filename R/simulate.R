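# Synthetic EEG simulation: band-limited latent sources, linear mixing,
# broadband noise and low-frequency drift.

# Unit-variance Gaussian noise band-limited to [band[1], band[2]] Hz via
# FFT masking. Consumes n draws from the current RNG stream.
bandlimited_noise <- function(n, fs, band) {
  e <- stats::rnorm(n)
  f <- stats::fft(e)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)  # fold to [0, fs/2]
  f[freq < band[1] | freq > band[2]] <- 0
  x <- Re(stats::fft(f, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Low-frequency drift: a demeaned Gaussian random walk rescaled to the
# requested standard deviation. Its power spectrum falls off as 1/f^2, so
# the bulk of its power sits below 1 Hz at session lengths of minutes,
# which is what the causal high-pass stage is there to remove.
drift_component <- function(n, amplitude) {
  w <- cumsum(stats::rnorm(n))
  w <- w - mean(w)
  s <- stats::sd(w)
  if (s == 0) return(rep(0, n))
  w / s * amplitude
}

#' Simulate one EEG recording under a coupling model
#'
#' Draws independent unit-variance latent sources band-limited to the
#' model's source band (4-30 Hz by default), mixes them with the model's
#' weights, and adds per-channel broadband Gaussian noise and a
#' low-frequency random-walk drift. After the standard preprocessing
#' (high-pass removes the drift, band-pass leaves sources intact) the
#' empirical channel correlations converge to
#' [analytic_channel_correlation()] of the model.
#'
#' Fully deterministic given `(model, script, fs, seed)`.
#'
#' @param model A [make_regime_config()] coupling model.
#' @param script A [task_script()]; its total duration sets the length.
#' @param fs Sampling rate in samples/s.
#' @param seed Integer seed.
#' @param subject_id Subject identifier stored in the recording.
#' @return An `eeg_recording`.
#' @export
#' @examples
#' rec <- simulate_recording(make_regime_config("KATA", 1), kata_script(),
#'                           fs = 128, seed = 1, subject_id = "S01")
simulate_recording <- function(model, script, fs = 128, seed = 1L,
                               subject_id = "sim") {
  stopifnot(inherits(model, "coupling_model"), inherits(script, "task_script"))
  if (fs <= 0) stop("fs must be positive")
  n <- round(fs * script$total_duration)
  if (n < 1) stop("non-positive recording duration")
  W <- model$mixing_weights
  k <- ncol(W)
  nc <- nrow(W)
  data <- with_seed(seed, {
    S <- matrix(0, k, n)
    for (i in seq_len(k)) {
      S[i, ] <- bandlimited_noise(n, fs, model$source_spectrum)
    }
    noise <- matrix(stats::rnorm(nc * n), nc, n) * model$noise_sd
    drift <- t(vapply(seq_len(nc),
                      function(i) drift_component(n, model$drift_amplitude),
                      numeric(n)))
    W %*% S + noise + drift
  })
  eeg_recording(data, fs = fs, subject_id = subject_id,
                task = script$task, script = script, seed = seed)
}

#' Simulate a cohort of subjects
#'
#' Each subject contributes one recording per task, by default a KATA and
#' a (CPD)nA session with the matching regime preset and per-subject
#' jitter of coupling strengths (see [make_regime_config()]). Passing
#' `regimes = c(KATA = "control", CPDnA = "control")` produces a null
#' cohort in which the two task labels carry no coupling difference.
#'
#' @param n_subjects Number of subjects (>= 1); the study design uses 24.
#' @param fs Sampling rate in samples/s.
#' @param seed Integer master seed; per-recording seeds are derived from
#'   it, so the cohort is reproducible as a whole.
#' @param regimes Named character vector: task label -> regime preset.
#' @return List of `eeg_recording` (2 per subject, tasks interleaved).
#' @export
make_cohort <- function(n_subjects, fs = 128, seed = 1L,
                        regimes = c(KATA = "KATA", CPDnA = "CPDnA")) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop("n_subjects must be >= 1")
  }
  n_subjects <- as.integer(n_subjects)
  tasks <- names(regimes)
  if (is.null(tasks) || any(tasks == "")) {
    stop("regimes must be a named vector: task label -> regime")
  }
  seeds <- matrix(derive_seeds(seed, 2L * n_subjects * length(tasks)),
                  nrow = length(tasks))
  out <- vector("list", n_subjects * length(tasks))
  idx <- 1L
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (t in seq_along(tasks)) {
      col <- (s - 1L) * 2L + 1L
      model <- make_regime_config(regimes[[t]], seed = seeds[t, col])
      script <- script_for_task(tasks[t])
      out[[idx]] <- simulate_recording(model, script, fs = fs,
                                       seed = seeds[t, col + 1L],
                                       subject_id = sid)
      idx <- idx + 1L
    }
  }
  out
}
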