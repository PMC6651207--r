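# Convolutional soft sensor, implemented from scratch in vectorized R:
# im2col convolution + ReLU + max pooling blocks, flatten, concatenation
# of the shallow-feature vector, one hidden dense layer and a softmax
# output, trained with Adam on cross-entropy. Images are tiny (5 x 128 x 3),
# so BLAS matrix products carry the whole computation.

#' Soft sensor configuration
#'
#' @param conv_blocks List of blocks, each `list(filters, kernel, pool)`.
#'   Kernels are square but clipped to the remaining spatial extent;
#'   pooling is `pool` x `pool` with stride = size, falling back to height
#'   1 when the feature map is shorter than the pool.
#' @param dense_units Width of the hidden fully connected layer.
#' @param learning_rate Adam step size.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param seed Master seed for weight init, shuffling, and splitting.
#' @param shallow_features Names of the per-channel shallow features
#'   merged at the dense layer (see [shallow_features()]).
#' @param instance_norm Standardize each channel plane of each input
#'   image to zero mean and unit variance (and map the shallow features
#'   consistently) before the first convolution. The per-recording
#'   min-max normalization leaves an arbitrary affine gain per channel
#'   that acts as a recording fingerprint; zero-lag correlation -- the
#'   quantity that separates the behavioral patterns -- is invariant to
#'   it, so this input layer removes the nuisance without touching the
#'   signal. On by default.
#' @return A `soft_sensor_config`.
#' @export
soft_sensor_config <- function(conv_blocks = list(
                                 list(filters = 32L, kernel = 3L, pool = 2L),
                                 list(filters = 64L, kernel = 3L, pool = 2L)),
                               dense_units = 128L, learning_rate = 1e-3,
                               epochs = 10L, batch_size = 32L, seed = 1L,
                               shallow_features = c("mean", "sd", "theta",
                                                    "alpha", "beta"),
                               instance_norm = TRUE) {
  stopifnot(length(conv_blocks) >= 1, epochs >= 1, dense_units >= 1,
            batch_size >= 1, learning_rate >= 0)
  for (b in conv_blocks) {
    stopifnot(b$filters >= 1, b$kernel >= 1, b$pool >= 1)
  }
  structure(list(conv_blocks = conv_blocks, dense_units = as.integer(dense_units),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 shallow_features = shallow_features,
                 instance_norm = isTRUE(instance_norm)),
            class = "soft_sensor_config")
}

# Input instance normalization: standardize every channel plane (pixel
# row x color plane) of every image to mean 0, sd 1 over its 1-s window;
# all-zero (null-channel) planes stay zero. Shallow features are mapped
# to their standardized-signal equivalents: mean -> 0, sd -> 1, band
# powers -> band power / variance (the scale-free band fraction).
instance_norm_images <- function(images, input_shape) {
  H <- input_shape[1]; W <- input_shape[2]; C <- input_shape[3]
  for (p in seq_len(C)) {
    for (r in seq_len(H)) {
      cols <- r + (seq_len(W) - 1L) * H + (p - 1L) * H * W
      sub <- images[, cols, drop = FALSE]
      m <- rowMeans(sub)
      s <- sqrt(pmax(rowMeans(sub^2) - m^2, 0))
      s[s < 1e-9] <- 1
      images[, cols] <- (sub - m) / s
    }
  }
  images
}

instance_norm_features <- function(features) {
  per_ch <- 5L   # (mean, sd, theta, alpha, beta) per channel
  n_ch <- ncol(features) / per_ch
  for (ch in seq_len(n_ch)) {
    base <- (ch - 1L) * per_ch
    v <- pmax(features[, base + 2L]^2, 1e-12)   # channel variance
    features[, base + 3L:5L] <- features[, base + 3L:5L] / v
    features[, base + 1L] <- 0
    features[, base + 2L] <- 1
  }
  features
}

# Geometry of every layer for a given input shape; includes the im2col
# index matrix (positions x kernel-elements) per conv block.
conv_geometry <- function(input_shape, config) {
  H <- input_shape[1]; W <- input_shape[2]; C <- input_shape[3]
  blocks <- list()
  for (bi in seq_along(config$conv_blocks)) {
    b <- config$conv_blocks[[bi]]
    kh <- min(b$kernel, H); kw <- min(b$kernel, W)
    OH <- H - kh + 1L; OW <- W - kw + 1L
    if (b$pool > OW) {
      stop(sprintf("block %d: pooling size %d exceeds feature-map width %d",
                   bi, b$pool, OW))
    }
    ph <- if (b$pool > OH) 1L else b$pool
    pw <- b$pool
    PH <- OH %/% ph; PW <- OW %/% pw
    K <- kh * kw * C
    P <- OH * OW
    idx <- matrix(0L, P, K)
    for (c in seq_len(C)) {
      for (dw in seq_len(kw)) {
        for (dh in seq_len(kh)) {
          k <- dh + (dw - 1L) * kh + (c - 1L) * kh * kw
          oh <- rep(seq_len(OH), OW)
          ow <- rep(seq_len(OW), each = OH)
          idx[, k] <- (oh + dh - 1L) + (ow + dw - 2L) * H + (c - 1L) * H * W
        }
      }
    }
    blocks[[bi]] <- list(Cin = C, H = H, W = W, kh = kh, kw = kw,
                         OH = OH, OW = OW, ph = ph, pw = pw,
                         PH = PH, PW = PW, K = K, P = P,
                         filters = as.integer(b$filters),
                         idx_vec = as.vector(idx))
    H <- PH; W <- PW; C <- as.integer(b$filters)
  }
  list(blocks = blocks, flat_dim = H * W * C)
}

#' Build an untrained soft sensor model
#'
#' Architecture: `[conv -> ReLU -> max-pool] x blocks -> flatten ->
#' concat(shallow features) -> dense + ReLU -> softmax`. Weights use
#' seeded He-normal initialization; the parameter count is reported via a
#' message.
#'
#' @param config A [soft_sensor_config()].
#' @param input_shape `c(rows, width, 3)`; `c(5, 128, 3)` for the default
#'   montage at 128 samples/s.
#' @param n_shallow Length of the shallow-feature vector (70 by default).
#' @param n_classes Number of output classes.
#' @return A `soft_sensor` model object.
#' @export
build_model <- function(config = soft_sensor_config(),
                        input_shape = c(5L, 128L, 3L),
                        n_shallow = 70L, n_classes = 2L) {
  geom <- conv_geometry(input_shape, config)
  params <- with_seed(config$seed, {
    p <- list(conv = list())
    for (bi in seq_along(geom$blocks)) {
      g <- geom$blocks[[bi]]
      p$conv[[bi]] <- list(
        W = matrix(stats::rnorm(g$K * g$filters, sd = sqrt(2 / g$K)),
                   g$K, g$filters),
        b = numeric(g$filters))
    }
    d_in <- geom$flat_dim + n_shallow
    p$dense1 <- list(
      W = matrix(stats::rnorm(d_in * config$dense_units,
                              sd = sqrt(2 / d_in)), d_in, config$dense_units),
      b = numeric(config$dense_units))
    p$dense2 <- list(
      W = matrix(stats::rnorm(config$dense_units * n_classes,
                              sd = sqrt(2 / config$dense_units)),
                 config$dense_units, n_classes),
      b = numeric(n_classes))
    p
  })
  n_par <- sum(vapply(params$conv, function(x) length(x$W) + length(x$b),
                      numeric(1))) +
    length(params$dense1$W) + length(params$dense1$b) +
    length(params$dense2$W) + length(params$dense2$b)
  message(sprintf("soft sensor: %d conv block(s), %s parameters",
                  length(geom$blocks), format(n_par, big.mark = ",")))
  structure(list(config = config, input_shape = input_shape,
                 n_shallow = as.integer(n_shallow),
                 n_classes = as.integer(n_classes),
                 geom = geom, params = params,
                 feature_stats = NULL, train_subjects = NULL,
                 classes = NULL),
            class = "soft_sensor")
}

# Max pool over dim d (2 = height, 3 = width) of a (B, H, W, F) array with
# stride = size; returns pooled array and argmax masks (first maximum
# claims the gradient). The stride-2 case, the only one the default
# architecture uses, is special-cased with a single comparison mask.
pool_max <- function(arr, d, p, n_out) {
  if (p == 1L) return(list(arr = arr, masks = NULL))
  slice <- function(k) {
    s <- seq.int(k, p * n_out, by = p)
    if (d == 2L) arr[, s, , , drop = FALSE] else arr[, , s, , drop = FALSE]
  }
  if (p == 2L) {
    a1 <- slice(1L); a2 <- slice(2L)
    m1 <- a1 >= a2
    return(list(arr = pmax(a1, a2), masks = m1))
  }
  pooled <- slice(1L)
  for (k in 2:p) pooled <- pmax(pooled, slice(k))
  masks <- vector("list", p)
  claimed <- array(FALSE, dim(pooled))
  for (k in seq_len(p)) {
    m <- (slice(k) == pooled) & !claimed
    claimed <- claimed | m
    masks[[k]] <- m
  }
  list(arr = pooled, masks = masks)
}

pool_max_backward <- function(d_pooled, masks, d, p, dim_pre) {
  if (is.null(masks)) return(d_pooled)
  dpre <- array(0, dim_pre)
  n_out <- dim(d_pooled)[d]
  assign_slice <- function(k, g) {
    s <- seq.int(k, p * n_out, by = p)
    if (d == 2L) dpre[, s, , ] <<- g else dpre[, , s, ] <<- g
  }
  if (p == 2L) {
    assign_slice(1L, d_pooled * masks)
    assign_slice(2L, d_pooled * !masks)
    return(dpre)
  }
  for (k in seq_len(p)) assign_slice(k, d_pooled * masks[[k]])
  dpre
}

relu <- function(x) { x[x < 0] <- 0; x }

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass over a batch. Xb: B x (H*W*C) image matrix (column layout:
# row fastest, then column, then color plane, matching as.vector() of a
# readPNG array). Fb: B x n_shallow standardized features.
sensor_forward <- function(model, Xb, Fb, cache = FALSE) {
  B <- nrow(Xb)
  caches <- if (cache) vector("list", length(model$geom$blocks))
  for (bi in seq_along(model$geom$blocks)) {
    g <- model$geom$blocks[[bi]]
    pr <- model$params$conv[[bi]]
    M <- Xb[, g$idx_vec, drop = FALSE]
    dim(M) <- c(B * g$P, g$K)
    Z <- M %*% pr$W
    Z <- Z + rep(pr$b, each = nrow(Z))
    # max pooling commutes with the (monotone) ReLU; pooling first keeps
    # the nonlinearity on the reduced map
    dim(Z) <- c(B, g$OH, g$OW, g$filters)
    hp <- pool_max(Z, 2L, g$ph, g$PH)
    wp <- pool_max(hp$arr, 3L, g$pw, g$PW)
    out <- relu(wp$arr)
    if (cache) {
      caches[[bi]] <- list(M = M, relu_mask = wp$arr > 0,
                           hmasks = hp$masks, wmasks = wp$masks,
                           dim_post_h = dim(hp$arr), dim_pre_pool = dim(Z))
    }
    Xb <- out
    dim(Xb) <- c(B, g$PH * g$PW * g$filters)
  }
  A0 <- cbind(Xb, Fb)
  Z1 <- A0 %*% model$params$dense1$W
  Z1 <- Z1 + rep(model$params$dense1$b, each = B)
  H1 <- relu(Z1)
  Z2 <- H1 %*% model$params$dense2$W
  Z2 <- Z2 + rep(model$params$dense2$b, each = B)
  probs <- softmax_rows(Z2)
  list(probs = probs,
       cache = if (cache) list(conv = caches, A0 = A0, H1 = H1,
                               relu1 = Z1 > 0))
}

# Backward pass; returns gradients with the same structure as params.
sensor_backward <- function(model, fwd, Y) {
  B <- nrow(Y)
  grads <- list(conv = vector("list", length(model$geom$blocks)))
  dZ2 <- (fwd$probs - Y) / B
  grads$dense2 <- list(W = crossprod(fwd$cache$H1, dZ2), b = colSums(dZ2))
  dH1 <- tcrossprod(dZ2, model$params$dense2$W)
  dZ1 <- dH1 * fwd$cache$relu1
  grads$dense1 <- list(W = crossprod(fwd$cache$A0, dZ1), b = colSums(dZ1))
  dA0 <- tcrossprod(dZ1, model$params$dense1$W)
  d_flat <- dA0[, seq_len(model$geom$flat_dim), drop = FALSE]
  for (bi in rev(seq_along(model$geom$blocks))) {
    g <- model$geom$blocks[[bi]]
    cc <- fwd$cache$conv[[bi]]
    d_out <- d_flat
    dim(d_out) <- c(B, g$PH, g$PW, g$filters)
    d_out <- d_out * cc$relu_mask
    d_hp <- pool_max_backward(d_out, cc$wmasks, 3L, g$pw, cc$dim_post_h)
    dZ <- pool_max_backward(d_hp, cc$hmasks, 2L, g$ph, cc$dim_pre_pool)
    dim(dZ) <- c(B * g$P, g$filters)
    grads$conv[[bi]] <- list(W = crossprod(cc$M, dZ), b = colSums(dZ))
    if (bi > 1L) {
      dM <- tcrossprod(dZ, model$params$conv[[bi]]$W)
      gp <- model$geom$blocks[[bi - 1L]]
      L_in <- g$H * g$W * g$Cin
      dXb <- matrix(0, B, L_in)
      dMarr <- dM
      dim(dMarr) <- c(B, g$P, g$K)
      idx <- matrix(g$idx_vec, g$P, g$K)
      for (k in seq_len(g$K)) {
        cols <- idx[, k]
        dXb[, cols] <- dXb[, cols] + dMarr[, , k]
      }
      d_flat <- dXb
    }
  }
  grads
}

# One Adam step over the parameter tree.
adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state$conv)) state$conv <- vector("list", length(params$conv))
  upd <- function(p, g, s) {
    if (is.null(s)) s <- list(m = p * 0, v = p * 0)
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mh <- s$m / (1 - beta1^t)
    vh <- s$v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
  }
  for (bi in seq_along(params$conv)) {
    for (nm in c("W", "b")) {
      r <- upd(params$conv[[bi]][[nm]], grads$conv[[bi]][[nm]],
               state$conv[[bi]][[nm]])
      params$conv[[bi]][[nm]] <- r$p
      state$conv[[bi]][[nm]] <- r$s
    }
  }
  for (layer in c("dense1", "dense2")) {
    for (nm in c("W", "b")) {
      r <- upd(params[[layer]][[nm]], grads[[layer]][[nm]],
               state[[layer]][[nm]])
      params[[layer]][[nm]] <- r$p
      state[[layer]][[nm]] <- r$s
    }
  }
  list(params = params, state = state)
}

#' Class probabilities for a batch of encoded images
#'
#' @param model A `soft_sensor` (trained or untrained).
#' @param images Matrix, one image per row (flattened rows x width x 3
#'   array in \[0, 1\], see [load_image_dataset()]).
#' @param features Matrix of raw shallow features, one row per image;
#'   standardized internally with the model's stored training statistics
#'   (if any).
#' @return Matrix of class probabilities (rows sum to 1); columns named
#'   after `model$classes` when the model has been trained.
#' @export
predict_soft_sensor <- function(model, images, features,
                                chunk_size = 1024L) {
  stopifnot(inherits(model, "soft_sensor"),
            ncol(features) == model$n_shallow)
  if (model$config$instance_norm) {
    images <- instance_norm_images(images, model$input_shape)
    features <- instance_norm_features(features)
  }
  if (!is.null(model$feature_stats)) {
    features <- scale(features, center = model$feature_stats$center,
                      scale = model$feature_stats$scale)
  }
  n <- nrow(images)
  probs <- matrix(0, n, model$n_classes)
  for (from in seq(1L, n, by = chunk_size)) {
    to <- min(from + chunk_size - 1L, n)
    probs[from:to, ] <- sensor_forward(model, images[from:to, , drop = FALSE],
                                       features[from:to, , drop = FALSE])$probs
  }
  colnames(probs) <- model$classes
  probs
}

#' Train the soft sensor
#'
#' Mini-batch Adam on softmax cross-entropy. Per-epoch training and
#' validation accuracy and loss are recorded; the returned model carries
#' the weights of the epoch with the best validation accuracy (earliest
#' epoch on ties). All randomness (shuffling) derives from the config
#' seed; weight initialization was already seeded in [build_model()].
#'
#' @param model An untrained [build_model()] soft sensor.
#' @param dataset A [load_image_dataset()] list (`images`, `features`,
#'   `labels`, `subjects`).
#' @param split A [split_by_subject()] partition.
#' @return The trained `soft_sensor`, with a `history` data.frame
#'   (epoch, train_loss, train_acc, val_loss, val_acc) attached.
#' @export
train_soft_sensor <- function(model, dataset, split) {
  cfg <- model$config
  classes <- sort(unique(dataset$labels))
  stopifnot(length(classes) == model$n_classes)
  part <- function(subjects) which(dataset$subjects %in% subjects)
  tr <- part(split$train_subjects)
  va <- part(split$validation_subjects)
  if (length(tr) == 0 || length(va) == 0) {
    stop("empty train or validation partition")
  }
  Xtr <- dataset$images[tr, , drop = FALSE]
  Ftr_raw <- dataset$features[tr, , drop = FALSE]
  if (cfg$instance_norm) {
    Xtr <- instance_norm_images(Xtr, model$input_shape)
    Ftr_raw <- instance_norm_features(Ftr_raw)
  }
  ctr <- colMeans(Ftr_raw)
  scl <- apply(Ftr_raw, 2, stats::sd)
  scl[scl == 0] <- 1
  model$feature_stats <- list(center = ctr, scale = scl)
  model$classes <- classes
  model$train_subjects <- split$train_subjects

  Ftr <- scale(Ftr_raw, ctr, scl)
  ytr <- match(dataset$labels[tr], classes)
  Ytr <- diag(model$n_classes)[ytr, , drop = FALSE]
  Xva <- dataset$images[va, , drop = FALSE]
  Fva_raw <- dataset$features[va, , drop = FALSE]
  yva <- match(dataset$labels[va], classes)

  n <- length(tr)
  state <- list()
  t_step <- 0L
  best <- list(acc = -Inf, params = model$params, epoch = 0L)
  history <- data.frame()
  shuffle_seeds <- derive_seeds(cfg$seed, cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(shuffle_seeds[epoch], sample.int(n))
    ep_loss <- 0; ep_hits <- 0
    for (from in seq(1L, n, by = cfg$batch_size)) {
      to <- min(from + cfg$batch_size - 1L, n)
      bi <- ord[from:to]
      fwd <- sensor_forward(model, Xtr[bi, , drop = FALSE],
                            Ftr[bi, , drop = FALSE], cache = TRUE)
      Yb <- Ytr[bi, , drop = FALSE]
      p_true <- rowSums(fwd$probs * Yb)
      ep_loss <- ep_loss - sum(log(pmax(p_true, 1e-12)))
      ep_hits <- ep_hits + sum(max.col(fwd$probs) == ytr[bi])
      grads <- sensor_backward(model, fwd, Yb)
      t_step <- t_step + 1L
      st <- adam_step(model$params, grads, state, cfg$learning_rate, t_step)
      model$params <- st$params
      state <- st$state
    }
    vp <- predict_soft_sensor(model, Xva, Fva_raw)
    val_loss <- -mean(log(pmax(vp[cbind(seq_along(yva), yva)], 1e-12)))
    val_acc <- mean(max.col(vp) == yva)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / n, train_acc = ep_hits / n,
      val_loss = val_loss, val_acc = val_acc))
    message(sprintf(
      "epoch %d/%d: train loss %.4f acc %.4f | val loss %.4f acc %.4f",
      epoch, cfg$epochs, ep_loss / n, ep_hits / n, val_loss, val_acc))
    if (val_acc > best$acc) {
      best <- list(acc = val_acc, params = model$params, epoch = epoch)
    }
  }
  model$params <- best$params
  model$best_epoch <- best$epoch
  model$history <- history
  model
}

#' @export
print.soft_sensor <- function(x, ...) {
  cat(sprintf("Convolutional soft sensor (%d conv blocks, dense %d)\n",
              length(x$geom$blocks), x$config$dense_units))
  if (!is.null(x$classes)) {
    cat(sprintf("  trained on %d subjects, classes: %s (best epoch %d)\n",
                length(x$train_subjects), paste(x$classes, collapse = " vs "),
                x$best_epoch))
  } else cat("  untrained\n")
  invisible(x)
}
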