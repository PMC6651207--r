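test_that("regime presets realize the reported correlation structure analytically", {
  fr <- frontal_channels()
  for (regime in c("KATA", "CPDnA")) {
    C <- analytic_channel_correlation(make_regime_config(regime, seed = 1))
    off <- C[fr, fr][upper.tri(C[fr, fr])]
    expect_true(all(off >= 0.45))
    expect_gte(C["F7", "F3"], 0.85)
    expect_gte(C["F4", "F8"], 0.85)
  }
  Ck <- analytic_channel_correlation(make_regime_config("KATA", seed = 1))
  Cc <- analytic_channel_correlation(make_regime_config("CPDnA", seed = 1))
  tpj <- rbind(c("P7", "F7"), c("P7", "F3"), c("P8", "F4"), c("P8", "F8"))
  expect_true(all(Ck[tpj] >= 0.21 & Ck[tpj] <= 0.34))
  expect_true(all(Cc[tpj] >= 0.68 & Cc[tpj] <= 0.73))
  C0 <- analytic_channel_correlation(make_regime_config("control", seed = 1))
  expect_equal(unname(C0["P7", "F7"]), 0)
  expect_equal(unname(C0["P8", "F8"]), 0)
})

test_that("unknown regime labels are rejected with the valid set named", {
  expect_error(make_regime_config("HOSHIN", 1), "KATA, CPDnA, control")
})

test_that("analytic correlation matches closed-form cases and a Monte-Carlo oracle", {
  ch <- aes_montage()
  # identity mixing, zero noise -> identity correlation
  m_id <- eegkata:::new_coupling_model(diag(14), noise_sd = rep(0, 14),
                                       regime_label = "custom", targets = NULL)
  expect_equal(unclass(analytic_channel_correlation(m_id))[, ],
               diag(14), ignore_attr = TRUE)
  # two channels sharing one unit-weight source, zero noise -> corr 1
  W <- diag(14); W[2, 1] <- 1; W[2, 2] <- 0
  m_sh <- eegkata:::new_coupling_model(W, rep(0, 14), "custom", NULL)
  expect_equal(unname(analytic_channel_correlation(m_sh)[1, 2]), 1)
  # w_i . w_j = 0.5 with unit channel variances -> corr 0.5,
  # cross-checked against brute-force simulation of the mixing model:
  # channels 1 and 2 each load sqrt(0.5) on a shared source and sqrt(0.5)
  # on a private one.
  W <- cbind(diag(sqrt(0.5), 14), shared = 0)
  W[1, 15] <- sqrt(0.5)
  W[2, 15] <- sqrt(0.5)
  m <- eegkata:::new_coupling_model(W, rep(0, 14), "custom", NULL)
  C <- analytic_channel_correlation(m)
  expect_equal(unname(C[1, 2]), 0.5, tolerance = 1e-12)
  set.seed(99)
  n_mc <- 1e5
  S <- matrix(rnorm(n_mc * ncol(W)), ncol(W), n_mc)
  X <- W %*% S
  expect_lt(abs(cor(X[1, ], X[2, ]) - 0.5), 0.02)
})

test_that("zero-variance channels are rejected by the analytic oracle", {
  W <- diag(14); W[3, 3] <- 0
  m <- eegkata:::new_coupling_model(W, rep(0, 14), "custom", NULL)
  expect_error(analytic_channel_correlation(m), "zero-variance")
})

test_that("simulated recordings are deterministic and have the contracted length", {
  model <- make_regime_config("KATA", seed = 3)
  sc <- task_script("KATA", "KATA-I", 1)
  r1 <- simulate_recording(model, sc, fs = 128, seed = 7)
  r2 <- simulate_recording(model, sc, fs = 128, seed = 7)
  expect_identical(r1$data, r2$data)
  expect_equal(ncol(r1$data), 128)
  expect_equal(nrow(r1$data), 14)
  r3 <- simulate_recording(model, sc, fs = 128, seed = 8)
  expect_false(identical(r1$data, r3$data))
})

test_that("empirical correlations after preprocessing match the analytic oracle within 0.05", {
  wp <- analysis_window_pair()
  for (regime in c("KATA", "CPDnA")) {
    C_th <- analytic_channel_correlation(make_regime_config(regime, seed = 11))
    win <- if (regime == "KATA") wp$kata else wp$cpdna
    C_emp <- correlation_matrix(win)
    expect_lt(max(abs(unclass(C_emp) - unclass(C_th))), 0.05)
  }
})

test_that("cohorts have one recording per subject-task with jitter inside regime bounds", {
  expect_error(make_cohort(0), "n_subjects")
  cohort <- make_cohort(6, fs = 128, seed = 7)
  expect_length(cohort, 12)
  tasks <- vapply(cohort, `[[`, "", "task")
  expect_equal(sum(tasks == "KATA"), 6)
  expect_equal(sum(tasks == "CPDnA"), 6)
  subj <- vapply(cohort, `[[`, "", "subject_id")
  expect_equal(length(unique(subj)), 6)
  expect_length(make_cohort(1, seed = 1), 2)
})

test_that("per-subject jittered targets stay inside the printed regime intervals", {
  tpj <- rbind(c("P7", "F7"), c("P7", "F3"), c("P8", "F4"), c("P8", "F8"))
  seeds <- eegkata:::derive_seeds(123, 24)
  for (s in seeds) {
    Ck <- analytic_channel_correlation(make_regime_config("KATA", seed = s))
    Cc <- analytic_channel_correlation(make_regime_config("CPDnA", seed = s))
    expect_true(all(Ck[tpj] >= 0.21 & Ck[tpj] <= 0.34))
    expect_true(all(Cc[tpj] >= 0.68 & Cc[tpj] <= 0.73))
    expect_gte(min(Ck["F7", "F3"], Ck["F4", "F8"],
                   Cc["F7", "F3"], Cc["F4", "F8"]), 0.85)
  }
})

test_that("regimes stay separated across a 20-seed sweep", {
  fr <- frontal_channels()
  for (s in seq_len(20)) {
    Ck <- analytic_channel_correlation(make_regime_config("KATA", seed = s))
    Cc <- analytic_channel_correlation(make_regime_config("CPDnA", seed = s))
    expect_gte(min(Ck[fr, fr][upper.tri(diag(6))]), 0.45)
    expect_gte(min(Cc[fr, fr][upper.tri(diag(6))]), 0.45)
    expect_gte(Cc["P8", "F8"] - Ck["P8", "F8"], 0.3)
  }
})

test_that("most drift power lies below 1 Hz", {
  set.seed(1)
  n <- 128 * 300
  d <- eegkata:::drift_component(n, amplitude = 2)
  p <- Mod(stats::fft(d))^2
  half <- 2:(n %/% 2)
  freqs <- (half - 1) * 128 / n
  expect_gt(sum(p[half][freqs < 1]) / sum(p[half]), 0.9)
})
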