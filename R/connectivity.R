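#' Correlation matrices over montage channels
#'
#' Thin S3 wrapper around a symmetric matrix of channel-pair coefficients
#' in \[-1, 1\] with unit diagonal.
#'
#' @param values Symmetric numeric matrix.
#' @param channel_names Channel labels (row/column names).
#' @return A `correlation_matrix` (a matrix with a class attribute).
#' @export
new_correlation_matrix <- function(values, channel_names) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            nrow(values) == length(channel_names))
  if (max(abs(values - t(values))) > 1e-12) {
    stop("correlation matrix is not symmetric")
  }
  values <- (values + t(values)) / 2
  if (any(values < -1 - 1e-9) || any(values > 1 + 1e-9)) {
    stop("coefficients outside [-1, 1]")
  }
  values <- pmin(pmax(values, -1), 1)
  diag(values) <- 1
  dimnames(values) <- list(channel_names, channel_names)
  structure(values, class = c("correlation_matrix", "matrix", "array"))
}

#' Zero-lag (or lag-searched) cross-correlation of two signals
#'
#' At `max_lag = 0` this is the normalized zero-lag coefficient: the inner
#' product of the two mean-removed signals over the product of their
#' norms, i.e. the Pearson correlation. For `max_lag > 0` the coefficient
#' is computed at every lag in `[-max_lag, max_lag]` (over the overlapping
#' samples) and the value of largest magnitude is returned.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @param max_lag Maximum lag in samples (0 = zero-lag only, the default).
#' @return A single coefficient in \[-1, 1\].
#' @export
#' @examples
#' cross_correlation(sin(1:100), sin(1:100))   # 1
cross_correlation <- function(a, b, max_lag = 0L) {
  if (length(a) != length(b)) stop("signals must have equal length")
  n <- length(a)
  if (n < 2) stop("signals must have length >= 2")
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("signals must be finite")
  }
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("zero-variance input: correlation undefined")
  }
  coef_at <- function(lag) {
    if (lag >= 0) {
      x <- a[(1 + lag):n]; y <- b[1:(n - lag)]
    } else {
      x <- a[1:(n + lag)]; y <- b[(1 - lag):n]
    }
    xm <- x - mean(x); ym <- y - mean(y)
    den <- sqrt(sum(xm^2) * sum(ym^2))
    if (den == 0) return(0)
    sum(xm * ym) / den
  }
  if (max_lag == 0) return(coef_at(0L))
  vals <- vapply(seq.int(-max_lag, max_lag), coef_at, numeric(1))
  vals[which.max(abs(vals))]
}

#' Channel-pair correlation matrix of a recording
#'
#' Pairwise cross-correlation coefficients over the full analysis window
#' of the recording. With the default `max_lag = 0` this is the plain
#' correlation matrix of the channel time series.
#'
#' @param recording A (preprocessed) `eeg_recording`.
#' @param channels Subset of montage channels; default all 14.
#' @param max_lag Lag search radius in samples, see [cross_correlation()].
#' @return A `correlation_matrix`.
#' @export
correlation_matrix <- function(recording, channels = NULL, max_lag = 0L) {
  stopifnot(inherits(recording, "eeg_recording"))
  channels <- channels %||% recording$channel_names
  unknown <- setdiff(channels, recording$channel_names)
  if (length(unknown) > 0) {
    stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  }
  X <- recording$data[channels, , drop = FALSE]
  if (max_lag == 0) {
    C <- stats::cor(t(X))
  } else {
    k <- length(channels)
    C <- diag(1, k)
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (j > i) C[i, j] <- C[j, i] <-
            cross_correlation(X[i, ], X[j, ], max_lag)
      }
    }
  }
  new_correlation_matrix(C, channels)
}

#' The four region-coupling hypotheses
#'
#' Builds the default hypothesis set linking sensor-pair correlations to
#' the two problem-solving behavioral patterns. Sensors proxy cortical
#' regions: F3/F8 dorsolateral PFC, F7/F4 ventromedial PFC, P7/P8 left and
#' right temporoparietal junction (TPJ).
#'
#' * H1 (both tasks, executive engagement): all 15 pairs among AF3, F7,
#'   F3, AF4, F4, F8 correlate at >= 0.45.
#' * H2 (both tasks, goal-driven): the within-hemisphere pairs (F7,F3) and
#'   (F4,F8) correlate at >= 0.85.
#' * H3 (KATA, context-independent): the TPJ-frontal pairs (P7,F7),
#'   (P7,F3), (P8,F4), (P8,F8) correlate at <= 0.34.
#' * H4 ((CPD)nA, context-dependent): the same pairs correlate at >= 0.68.
#'
#' Comparisons are inclusive: a coefficient exactly at the threshold
#' counts as passing.
#'
#' @return List of `hypothesis_spec` objects (`id`, `pairs` 2-column
#'   matrix, `comparator`, `threshold`, `task`, `annotation`).
#' @export
default_hypotheses <- function() {
  fr <- frontal_channels()
  h1_pairs <- t(utils::combn(fr, 2))
  pair_mat <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  tpj_pairs <- pair_mat("P7", "F7", "P7", "F3", "P8", "F4", "P8", "F8")
  regions <- c(F7 = "vmPFC-L", F3 = "dlPFC-L", F4 = "vmPFC-R",
               F8 = "dlPFC-R", P7 = "TPJ-L", P8 = "TPJ-R",
               AF3 = "PFC-L", AF4 = "PFC-R")
  spec <- function(id, pairs, comparator, threshold, task, note) {
    structure(list(id = id, pairs = pairs, comparator = comparator,
                   threshold = threshold, task = task,
                   annotation = note, regions = regions),
              class = "hypothesis_spec")
  }
  list(
    spec("H1", h1_pairs, "all_ge", 0.45, "both",
         "frontal sensors mutually correlated (executive engagement)"),
    spec("H2", pair_mat("F7", "F3", "F4", "F8"), "all_ge", 0.85, "both",
         "dlPFC-vmPFC pairs strongly coupled (goal-driven)"),
    spec("H3", tpj_pairs, "all_le", 0.34, "KATA",
         "weak TPJ-frontal coupling (context-independent routine)"),
    spec("H4", tpj_pairs, "all_ge", 0.68, "CPDnA",
         "strong TPJ-frontal coupling (context-dependent routine)")
  )
}

# Evaluate one spec against one correlation matrix.
check_pairs <- function(cm, spec) {
  vals <- cm[spec$pairs]
  ok <- switch(spec$comparator,
               all_ge = all(vals >= spec$threshold),
               all_le = all(vals <= spec$threshold),
               stop("unknown comparator: ", spec$comparator))
  list(values = vals, pass = ok)
}

#' Evaluate the hypothesis set on a subject's two task matrices
#'
#' H1 and H2 are evaluated on both tasks and are supported only if both
#' pass; H3 is evaluated on the KATA matrix, H4 on the (CPD)nA matrix.
#' Per-pair coefficients are always reported alongside the verdict, since
#' coupling strength varies across pairs even when a hypothesis holds.
#'
#' @param kata,cpdna `correlation_matrix` objects over (at least) the
#'   channels each hypothesis needs, from the KATA and (CPD)nA analysis
#'   windows.
#' @param specs Hypothesis list, by default [default_hypotheses()].
#' @return List of `hypothesis_report` objects: `spec`, `per_pair` (a
#'   data.frame task/channel_a/channel_b/coefficient), `verdict`.
#' @export
evaluate_hypotheses <- function(kata, cpdna, specs = default_hypotheses()) {
  mats <- list(KATA = kata, CPDnA = cpdna)
  for (m in mats) {
    stopifnot(inherits(m, "correlation_matrix"))
  }
  lapply(specs, function(sp) {
    tasks <- if (sp$task == "both") c("KATA", "CPDnA") else sp$task
    needed <- unique(as.vector(sp$pairs))
    rows <- list()
    pass <- TRUE
    for (tk in tasks) {
      cm <- mats[[tk]]
      missing <- setdiff(needed, rownames(cm))
      if (length(missing) > 0) {
        stop(sp$id, ": matrix for ", tk, " lacks channel(s): ",
             paste(missing, collapse = ", "))
      }
      res <- check_pairs(cm, sp)
      pass <- pass && res$pass
      rows[[tk]] <- data.frame(task = tk, channel_a = sp$pairs[, 1],
                               channel_b = sp$pairs[, 2],
                               coefficient = res$values)
    }
    structure(list(spec = sp, per_pair = do.call(rbind, rows),
                   verdict = if (pass) "supported" else "not_supported"),
              class = "hypothesis_report")
  })
}

#' @export
print.hypothesis_report <- function(x, ...) {
  cat(sprintf("%s [%s]: %s\n", x$spec$id, x$spec$annotation, x$verdict))
  cat(sprintf("  comparator %s %.2f on %d pair(s)\n", x$spec$comparator,
              x$spec$threshold, nrow(x$spec$pairs)))
  rng <- range(x$per_pair$coefficient)
  cat(sprintf("  coefficients in [%.3f, %.3f]\n", rng[1], rng[2]))
  invisible(x)
}

#' Write a JSON connectivity report
#'
#' Serializes, per task, the full 14x14 correlation matrix plus the
#' per-hypothesis pair coefficients and verdicts.
#'
#' @param kata,cpdna Full-montage `correlation_matrix` objects.
#' @param reports Output of [evaluate_hypotheses()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_connectivity_report <- function(kata, cpdna, reports, path) {
  payload <- list(
    channels = rownames(kata),
    matrices = list(KATA = unclass(kata)[, ], CPDnA = unclass(cpdna)[, ]),
    hypotheses = lapply(reports, function(r) {
      list(id = r$spec$id, comparator = r$spec$comparator,
           threshold = r$spec$threshold, task = r$spec$task,
           verdict = r$verdict, pairs = r$per_pair)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Heat-map of a correlation matrix
#'
#' Simple image() heat-map of channel-pair coefficients, the package's
#' counterpart of the paired-sensor correlation panels.
#'
#' @param cm A `correlation_matrix`.
#' @param main Plot title.
#' @return `cm`, invisibly.
#' @export
plot_correlation_matrix <- function(cm, main = "channel cross-correlation") {
  k <- nrow(cm)
  graphics::image(seq_len(k), seq_len(k), t(unclass(cm))[, k:1],
                  zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                  main = main,
                  col = grDevices::hcl.colors(64, "Blue-Red 3"))
  graphics::axis(1, seq_len(k), rownames(cm), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(k), rev(rownames(cm)), las = 2, cex.axis = 0.7)
  invisible(cm)
}
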