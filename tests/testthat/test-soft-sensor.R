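test_that("shallow features have the contracted length and content", {
  seg <- random_segment()
  f <- shallow_features(seg)
  expect_length(f, 70)
  expect_equal(unname(f["AF3.mean"]), mean(seg$data["AF3", ]))
  expect_equal(unname(f["P8.sd"]), sd(seg$data["P8", ]))
  # constant channel: sd and band powers are zero
  seg$data["O1", ] <- 0.4
  f2 <- shallow_features(seg)
  expect_equal(unname(f2[c("O1.sd", "O1.theta", "O1.alpha", "O1.beta")]),
               rep(0, 4))
  # wrong sample count rejected
  bad <- seg; bad$data <- bad$data[, 1:100]
  expect_error(shallow_features(bad), "128")
})

test_that("a 10 Hz tone concentrates its power in the alpha band", {
  seg <- random_segment()
  t <- (0:127) / 128
  seg$data["F3", ] <- 0.5 + 0.4 * sin(2 * pi * 10 * t)
  f <- shallow_features(seg)
  expect_gt(f["F3.alpha"], 10 * f["F3.theta"])
  expect_gt(f["F3.alpha"], 10 * f["F3.beta"])
  # periodogram oracle: alpha power of a pure tone is its variance
  expect_equal(unname(f["F3.alpha"]), 0.4^2 / 2, tolerance = 1e-9)
})

test_that("subject splits are disjoint, seeded, and 20/2/2 at n = 24", {
  man <- data.frame(subject_id = rep(sprintf("S%02d", 1:24), each = 2),
                    task = rep(c("KATA", "CPDnA"), 24))
  sp <- split_by_subject(man, seed = 5)
  expect_length(sp$train_subjects, 20)
  expect_length(sp$test_subjects, 2)
  expect_length(sp$validation_subjects, 2)
  all_sub <- c(sp$train_subjects, sp$test_subjects, sp$validation_subjects)
  expect_equal(sort(all_sub), sort(unique(man$subject_id)))
  expect_equal(anyDuplicated(all_sub), 0L)
  expect_identical(split_by_subject(man, seed = 5), sp)
  expect_false(identical(split_by_subject(man, seed = 6), sp))
  expect_error(split_by_subject(man, ratios = c(0.5, 0.2, 0.2)), "sum")
  expect_error(split_by_subject(man[1:6, ], seed = 1), "at least 4")
})

test_that("confusion metrics satisfy the accuracy identity", {
  truth <- rep(c("KATA", "CPDnA"), each = 250)
  m <- confusion_metrics(truth, truth)
  expect_equal(m$ACC, 1)
  expect_equal(m$FP + m$FN, 0)
  m2 <- confusion_metrics(truth, rep("KATA", 500))
  expect_equal(m2$ACC, 0.5)
  set.seed(8)
  pred <- sample(c("KATA", "CPDnA"), 500, replace = TRUE)
  m3 <- confusion_metrics(truth, pred)
  expect_equal(m3$ACC, (m3$TP + m3$TN) / (m3$TP + m3$TN + m3$FP + m3$FN))
  expect_equal(m3$TP + m3$TN + m3$FP + m3$FN, 500)
})

test_that("an untrained model outputs normalized probabilities at chance accuracy", {
  model <- suppressMessages(build_model(soft_sensor_config(seed = 4)))
  set.seed(10)
  n <- 200
  imgs <- matrix(runif(n * 5 * 128 * 3), n)
  feats <- matrix(runif(n * 70), n)
  probs <- predict_soft_sensor(model, imgs, feats)
  expect_equal(rowSums(probs), rep(1, n), tolerance = 1e-12)
  model$classes <- c("A", "B")
  truth <- rep(c("A", "B"), each = n / 2)
  pred <- model$classes[max.col(probs)]
  expect_gte(mean(pred == truth), 0.4)
  expect_lte(mean(pred == truth), 0.6)
})

test_that("model geometry rejects pooling wider than the feature map", {
  cfg <- soft_sensor_config(conv_blocks = list(
    list(filters = 8L, kernel = 3L, pool = 200L)))
  expect_error(build_model(cfg), "pooling")
})

test_that("training learns a separable cohort and respects the seed", {
  ds <- small_dataset()
  sp <- split_by_subject(ds$manifest, seed = 2)
  cfg <- soft_sensor_config(epochs = 8, seed = 3)
  model <- suppressMessages(build_model(cfg))
  fit <- suppressMessages(train_soft_sensor(model, ds, sp))
  expect_equal(nrow(fit$history), 8)
  expect_gt(fit$history$train_acc[8], fit$history$train_acc[1] - 0.02)
  expect_gt(fit$history$train_acc[8], 0.95)
  expect_lt(min(fit$history$val_loss),
            fit$history$train_loss[1])
  # training is reproducible from the config seed
  fit2 <- suppressMessages(train_soft_sensor(
    suppressMessages(build_model(cfg)), ds, sp))
  expect_equal(fit$params, fit2$params)
  expect_equal(fit$history, fit2$history)
})

test_that("zero learning rate leaves accuracy at chance", {
  ds <- small_dataset()
  sp <- split_by_subject(ds$manifest, seed = 2)
  cfg <- soft_sensor_config(epochs = 1, learning_rate = 0, seed = 3)
  fit <- suppressMessages(train_soft_sensor(
    suppressMessages(build_model(cfg)), ds, sp))
  expect_gte(fit$history$val_acc[1], 0.35)
  expect_lte(fit$history$val_acc[1], 0.65)
})

test_that("evaluation refuses subject-level leakage", {
  ds <- small_dataset()
  sp <- split_by_subject(ds$manifest, seed = 2)
  cfg <- soft_sensor_config(epochs = 1, seed = 3)
  fit <- suppressMessages(train_soft_sensor(
    suppressMessages(build_model(cfg)), ds, sp))
  expect_error(evaluate_soft_sensor(fit, ds, sp$train_subjects[1]),
               "overlap")
  m <- evaluate_soft_sensor(fit, ds, sp$test_subjects)
  expect_equal(m$TP + m$TN + m$FP + m$FN, 500)
  expect_equal(m$ACC, (m$TP + m$TN) / 500)
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(1)
  cfg <- soft_sensor_config(conv_blocks = list(
    list(filters = 4L, kernel = 3L, pool = 2L),
    list(filters = 6L, kernel = 3L, pool = 2L)),
    dense_units = 8L, seed = 2)
  model <- suppressMessages(build_model(cfg, input_shape = c(5L, 16L, 3L),
                                        n_shallow = 6L))
  B <- 3
  X <- eegkata:::instance_norm_images(matrix(runif(B * 5 * 16 * 3), B),
                                      model$input_shape)
  Fb <- matrix(rnorm(B * 6), B)
  Y <- diag(2)[c(1, 2, 1), ]
  loss_fn <- function(m) {
    p <- eegkata:::sensor_forward(m, X, Fb)$probs
    -sum(log(rowSums(p * Y))) / B
  }
  fwd <- eegkata:::sensor_forward(model, X, Fb, cache = TRUE)
  gr <- eegkata:::sensor_backward(model, fwd, Y)
  eps <- 1e-6
  grad_of <- list(conv1.W = gr$conv[[1]]$W, conv2.W = gr$conv[[2]]$W,
                  conv2.b = gr$conv[[2]]$b, dense1.W = gr$dense1$W,
                  dense2.W = gr$dense2$W, dense2.b = gr$dense2$b)
  getset <- list(
    conv1.W = function(m, v) { if (missing(v)) m$params$conv[[1]]$W
      else { m$params$conv[[1]]$W <- v; m } },
    conv2.W = function(m, v) { if (missing(v)) m$params$conv[[2]]$W
      else { m$params$conv[[2]]$W <- v; m } },
    conv2.b = function(m, v) { if (missing(v)) m$params$conv[[2]]$b
      else { m$params$conv[[2]]$b <- v; m } },
    dense1.W = function(m, v) { if (missing(v)) m$params$dense1$W
      else { m$params$dense1$W <- v; m } },
    dense2.W = function(m, v) { if (missing(v)) m$params$dense2$W
      else { m$params$dense2$W <- v; m } },
    dense2.b = function(m, v) { if (missing(v)) m$params$dense2$b
      else { m$params$dense2$b <- v; m } })
  for (nm in names(grad_of)) {
    p <- getset[[nm]](model)
    idx <- sample(length(p), min(4, length(p)))
    for (i in idx) {
      up <- p; up[i] <- up[i] + eps
      dn <- p; dn[i] <- dn[i] - eps
      num <- (loss_fn(getset[[nm]](model, up)) -
                loss_fn(getset[[nm]](model, dn))) / (2 * eps)
      expect_equal(grad_of[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("%s[%d]", nm, i))
    }
  }
})
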