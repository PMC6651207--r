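test_that("zero-lag cross-correlation behaves as a correlation coefficient", {
  set.seed(1)
  a <- rnorm(200)
  expect_equal(cross_correlation(a, a), 1)
  expect_equal(cross_correlation(a, -a), -1)
  b <- rnorm(200)
  expect_equal(cross_correlation(a, b), cor(a, b))
  expect_error(cross_correlation(a, rep(1, 200)), "zero-variance")
  expect_error(cross_correlation(a, b[1:100]), "equal length")
})

test_that("lag search equals the brute-force maximum over shifted coefficients", {
  set.seed(2)
  for (rep in 1:5) {
    a <- rnorm(150)
    b <- c(rnorm(3), a[1:147]) + rnorm(150, sd = 0.5)  # b lags a by 3
    brute <- vapply(-5:5, function(l) {
      n <- length(a)
      if (l >= 0) cor(a[(1 + l):n], b[1:(n - l)]) else
        cor(a[1:(n + l)], b[(1 - l):n])
    }, numeric(1))
    expect_equal(cross_correlation(a, b, max_lag = 5),
                 brute[which.max(abs(brute))])
  }
})

test_that("cross-correlation is symmetric and invariant to positive affine rescaling", {
  set.seed(3)
  for (rep in 1:10) {
    a <- rnorm(100); b <- rnorm(100)
    expect_equal(cross_correlation(a, b), cross_correlation(b, a))
    expect_equal(cross_correlation(2.5 * a + 7, b),
                 cross_correlation(a, b), tolerance = 1e-12)
  }
})

test_that("the correlation matrix agrees with pairwise calls and flags bad channels", {
  wp <- analysis_window_pair()
  win <- wp$kata
  sub <- c("AF3", "F7", "P8", "O1")
  cm <- correlation_matrix(win, channels = sub)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(unname(cm[i, j]),
                 cross_correlation(win$data[sub[i], ], win$data[sub[j], ]),
                 tolerance = 1e-12)
  }
  expect_equal(unclass(cm), t(unclass(cm)), ignore_attr = TRUE)
  expect_equal(unname(diag(cm)), rep(1, 4))
  expect_error(correlation_matrix(win, channels = c("AF3", "XX")), "XX")
  # duplicated signal in two channels -> off-diagonal 1
  dup <- win
  dup$data["F7", ] <- dup$data["AF3", ]
  expect_equal(unname(correlation_matrix(dup, c("AF3", "F7"))[1, 2]), 1)
})

test_that("lag-searched matrices remain symmetric and match pairwise calls", {
  wp <- analysis_window_pair()
  win <- wp$kata
  win$data <- win$data[, 1:500]
  cm <- correlation_matrix(win, channels = c("AF3", "F7", "P8"), max_lag = 3)
  expect_equal(unname(cm["AF3", "F7"]),
               cross_correlation(win$data["AF3", ], win$data["F7", ], 3))
  expect_equal(unclass(cm), t(unclass(cm)), ignore_attr = TRUE)
})

test_that("the default hypothesis set encodes the four regional couplings", {
  hs <- default_hypotheses()
  ids <- vapply(hs, function(h) h$id, "")
  expect_equal(ids, c("H1", "H2", "H3", "H4"))
  expect_equal(nrow(hs[[1]]$pairs), choose(6, 2))
  expect_equal(nrow(hs[[2]]$pairs), 2)
  expect_equal(hs[[3]]$pairs, hs[[4]]$pairs)
  expect_equal(hs[[3]]$comparator, "all_le")
  expect_equal(hs[[4]]$comparator, "all_ge")
  expect_equal(hs[[3]]$task, "KATA")
  expect_equal(hs[[4]]$task, "CPDnA")
  expect_true(all(unlist(lapply(hs, function(h) h$pairs)) %in% aes_montage()))
})

test_that("all four hypotheses are supported on regime-preset synthetic data", {
  wp <- analysis_window_pair()
  reports <- evaluate_hypotheses(correlation_matrix(wp$kata),
                                 correlation_matrix(wp$cpdna))
  verdicts <- vapply(reports, `[[`, "", "verdict")
  expect_equal(unname(verdicts), rep("supported", 4))
  # per-pair values are reported, not just verdicts
  expect_true(all(vapply(reports, function(r) nrow(r$per_pair) > 0, NA)))
})

test_that("control-regime coupling fails the strong-coupling hypothesis", {
  wp <- analysis_window_pair()
  ctrl <- simulate_recording(make_regime_config("control", seed = 5),
                             cpdna_script(), fs = 128, seed = 6)
  ctrl_cm <- correlation_matrix(
    subtask_window(suppressMessages(preprocess(ctrl)), "Plan"))
  reports <- evaluate_hypotheses(correlation_matrix(wp$kata), ctrl_cm)
  expect_equal(reports[[4]]$verdict, "not_supported")
})

test_that("thresholds are inclusive and monotone in the verdict", {
  C <- unclass(analytic_channel_correlation(make_regime_config("CPDnA", 1)))[, ]
  # force one H1 pair just under threshold -> not supported
  eps <- 1e-6
  C_low <- C
  C_low["AF3", "F7"] <- C_low["F7", "AF3"] <- 0.45 - eps
  cm_low <- new_correlation_matrix(C_low, aes_montage())
  cm_at <- C
  cm_at["AF3", "F7"] <- cm_at["F7", "AF3"] <- 0.45
  cm_at <- new_correlation_matrix(cm_at, aes_montage())
  h1 <- default_hypotheses()[[1]]
  expect_equal(evaluate_hypotheses(cm_low, cm_low, list(h1))[[1]]$verdict,
               "not_supported")
  expect_equal(evaluate_hypotheses(cm_at, cm_at, list(h1))[[1]]$verdict,
               "supported")
  # raising an all_ge threshold can only flip supported -> not_supported
  cm <- new_correlation_matrix(C, aes_montage())
  for (thr in c(0.2, 0.45, 0.6, 0.95)) {
    h_lo <- h1; h_lo$threshold <- thr
    h_hi <- h1; h_hi$threshold <- thr + 0.04
    v_lo <- evaluate_hypotheses(cm, cm, list(h_lo))[[1]]$verdict
    v_hi <- evaluate_hypotheses(cm, cm, list(h_hi))[[1]]$verdict
    expect_false(v_lo == "not_supported" && v_hi == "supported")
  }
})

test_that("hypothesis evaluation rejects matrices missing needed channels", {
  wp <- analysis_window_pair()
  cm_small <- correlation_matrix(wp$kata, channels = c("AF3", "F7"))
  expect_error(evaluate_hypotheses(cm_small, cm_small), "lacks channel")
})
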