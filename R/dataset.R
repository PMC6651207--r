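#' Load an encoded image dataset into memory
#'
#' Reads every PNG listed in a [build_image_dataset()] manifest into a
#' flat image matrix (one row per image, values in \[0, 1\]) and computes
#' the shallow-feature matrix from the decoded segments.
#'
#' @param manifest Manifest data.frame with a `dir` attribute, or a
#'   dataset directory (then read via [read_image_manifest()]).
#' @return List: `images` (n x 1920 for the default geometry), `features`
#'   (n x 70), `labels`, `subjects`, `manifest`.
#' @export
load_image_dataset <- function(manifest) {
  if (is.character(manifest)) manifest <- read_image_manifest(manifest)
  dir <- attr(manifest, "dir")
  n <- nrow(manifest)
  first <- png::readPNG(file.path(dir, manifest$path[1]))
  images <- matrix(0, n, length(first))
  features <- NULL
  for (i in seq_len(n)) {
    px <- if (i == 1) first else png::readPNG(file.path(dir, manifest$path[i]))
    images[i, ] <- as.vector(px)
    seg <- decode_image(px)
    fv <- shallow_features(seg)
    if (is.null(features)) {
      features <- matrix(0, n, length(fv),
                         dimnames = list(NULL, names(fv)))
    }
    features[i, ] <- fv
  }
  list(images = images, features = features,
       labels = as.character(manifest$task),
       subjects = as.character(manifest$subject_id),
       manifest = manifest)
}

#' Subject-wise train/test/validation split
#'
#' Subjects (never individual segments) are assigned at random to the
#' three partitions, so no subject's images can leak between training and
#' evaluation. With the default 0.8/0.1/0.1 ratios and 24 subjects the
#' split is 20/2/2.
#'
#' @param manifest Image-dataset manifest (or anything with `subject_id`
#'   and `task` columns).
#' @param ratios Train/test/validation proportions summing to 1.
#' @param seed Integer seed for the random assignment.
#' @return A `dataset_split`: list of `train_subjects`, `test_subjects`,
#'   `validation_subjects`, plus the `ratios`.
#' @export
split_by_subject <- function(manifest, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-9 || length(ratios) != 3) {
    stop("ratios must be three proportions summing to 1")
  }
  subjects <- sort(unique(as.character(manifest$subject_id)))
  n <- length(subjects)
  if (n < 4) stop("need at least 4 subjects to split")
  n_test <- max(1L, round(ratios[2] * n))
  n_val <- max(1L, round(ratios[3] * n))
  n_train <- n - n_test - n_val
  if (n_train < 1) stop("ratios leave no training subjects")
  shuffled <- with_seed(seed, sample(subjects))
  split <- structure(
    list(train_subjects = sort(shuffled[seq_len(n_train)]),
         test_subjects = sort(shuffled[n_train + seq_len(n_test)]),
         validation_subjects = sort(shuffled[n_train + n_test +
                                               seq_len(n_val)]),
         ratios = ratios),
    class = "dataset_split")
  for (part in c("train_subjects", "test_subjects", "validation_subjects")) {
    tasks <- unique(manifest$task[manifest$subject_id %in% split[[part]]])
    if (length(tasks) < length(unique(manifest$task))) {
      stop("partition ", part, " does not contain every class")
    }
  }
  split
}

#' Confusion counts and accuracy
#'
#' Builds the 2x2 confusion matrix and the accuracy
#' `ACC = (TP + TN) / (TP + TN + FP + FN)`, with KATA as the positive
#' class, plus per-class rates.
#'
#' @param truth,predicted Character vectors of class labels.
#' @param positive The positive class label.
#' @return A `sensor_metrics` list: `TP`, `TN`, `FP`, `FN`, `ACC`,
#'   `TPR`, `TNR`, `FPR`, `FNR`, and the `confusion` matrix.
#' @export
confusion_metrics <- function(truth, predicted, positive = "KATA") {
  stopifnot(length(truth) == length(predicted))
  tp <- sum(truth == positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  conf <- matrix(c(tp, fp, fn, tn), 2, 2,
                 dimnames = list(truth = c(positive, "other"),
                                 predicted = c(positive, "other")))
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 ACC = (tp + tn) / (tp + tn + fp + fn),
                 TPR = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 TNR = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 FPR = if (tn + fp > 0) fp / (tn + fp) else NA_real_,
                 FNR = if (tp + fn > 0) fn / (tp + fn) else NA_real_,
                 confusion = conf, positive = positive),
            class = "sensor_metrics")
}

#' @export
print.sensor_metrics <- function(x, ...) {
  cat(sprintf("ACC = %.4f  (TP %d, TN %d, FP %d, FN %d; positive = %s)\n",
              x$ACC, x$TP, x$TN, x$FP, x$FN, x$positive))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a trained soft sensor on held-out subjects
#'
#' Rejects any overlap between the model's training subjects and the
#' requested evaluation subjects (subject-level leakage is impossible by
#' construction).
#'
#' @param model A trained `soft_sensor`.
#' @param dataset A [load_image_dataset()] list covering the subjects.
#' @param subjects Held-out subject ids (e.g. `split$test_subjects`).
#' @return A `sensor_metrics` object (see [confusion_metrics()]), with
#'   the predictions attached as attribute `predictions`.
#' @export
evaluate_soft_sensor <- function(model, dataset, subjects) {
  stopifnot(inherits(model, "soft_sensor"))
  if (is.null(model$classes)) stop("model has not been trained")
  overlap <- intersect(subjects, model$train_subjects)
  if (length(overlap) > 0) {
    stop("evaluation subjects overlap training set: ",
         paste(overlap, collapse = ", "))
  }
  idx <- which(dataset$subjects %in% subjects)
  if (length(idx) == 0) stop("no images for the requested subjects")
  probs <- predict_soft_sensor(model, dataset$images[idx, , drop = FALSE],
                               dataset$features[idx, , drop = FALSE])
  pred <- model$classes[max.col(probs)]
  m <- confusion_metrics(dataset$labels[idx], pred, positive = "KATA")
  attr(m, "predictions") <- data.frame(
    subject_id = dataset$subjects[idx], truth = dataset$labels[idx],
    predicted = pred)
  m
}
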