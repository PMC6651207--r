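# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# One preprocessed subject per regime preset, 250-s analysis windows.
analysis_window_pair <- function() {
  fixture("window_pair", function() {
    kata <- simulate_recording(make_regime_config("KATA", seed = 11),
                               kata_script(), fs = 128, seed = 21,
                               subject_id = "S01")
    cpdna <- simulate_recording(make_regime_config("CPDnA", seed = 11),
                                cpdna_script(), fs = 128, seed = 22,
                                subject_id = "S01")
    suppressMessages(list(
      kata = subtask_window(preprocess(kata), "KATA-III"),
      cpdna = subtask_window(preprocess(cpdna), "Plan")))
  })
}

# Small 4-subject preprocessed cohort.
small_cohort <- function() {
  fixture("small_cohort", function() {
    suppressMessages(lapply(make_cohort(4, fs = 128, seed = 42), preprocess))
  })
}

# Image dataset built from the small cohort, loaded into memory.
small_dataset <- function() {
  fixture("small_dataset", function() {
    dir <- file.path(tempdir(), "eegkata-small-images")
    manifest <- build_image_dataset(small_cohort(), dir)
    load_image_dataset(manifest)
  })
}

# A normalized random segment over the full montage.
random_segment <- function(seed = 5, fs = 128) {
  set.seed(seed)
  m <- matrix(stats::runif(14 * fs), 14, fs,
              dimnames = list(aes_montage(), NULL))
  structure(list(subject_id = "X", task = "KATA", subtask = "KATA-III",
                 index = 1L, fs = fs, data = m),
            class = "eeg_segment")
}

# Full study-scale image dataset (24 subjects, 12,000 images), built once
# and shared by the acceptance checks.
full_dataset_dir <- function() {
  fixture("full_dataset_dir", function() {
    dir <- file.path(tempdir(), "eegkata-full-images")
    cohort <- make_cohort(24, fs = 128, seed = 1)
    prep <- suppressMessages(lapply(cohort, preprocess))
    build_image_dataset(prep, dir)
    dir
  })
}
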