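#' Task scripts: ordered sub-task intervals
#'
#' A task script lists the timed sub-tasks of one 300-s problem-solving
#' session. The two study presets are:
#'
#' * `KATA`: KATA-I (10 s), KATA-II (40 s), KATA-III (250 s)
#' * `CPDnA`: Check (10 s), Plan (250 s), Do (40 s)
#'
#' The long sub-task of each session (KATA-III, Plan) is the analysis
#' window used for connectivity and for the image dataset.
#'
#' @param task Task label, `"KATA"` or `"CPDnA"`, or arbitrary for custom
#'   scripts.
#' @param labels Character vector of sub-task labels.
#' @param durations Numeric vector of sub-task durations in seconds, same
#'   length as `labels`, all positive.
#' @return A `task_script` object: list with `task`, `labels`, `durations`,
#'   `total_duration` (s).
#' @export
#' @examples
#' kata_script()
#' cpdna_script()
task_script <- function(task, labels, durations) {
  stopifnot(length(labels) == length(durations), length(labels) >= 1)
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop("sub-task durations must be positive and finite")
  }
  structure(
    list(task = task, labels = as.character(labels),
         durations = as.numeric(durations),
         total_duration = sum(durations)),
    class = "task_script"
  )
}

#' @rdname task_script
#' @export
kata_script <- function() {
  task_script("KATA", c("KATA-I", "KATA-II", "KATA-III"), c(10, 40, 250))
}

#' @rdname task_script
#' @export
cpdna_script <- function() {
  task_script("CPDnA", c("Check", "Plan", "Do"), c(10, 250, 40))
}

# Preset script for a task label.
script_for_task <- function(task) {
  switch(task,
    KATA = kata_script(),
    CPDnA = cpdna_script(),
    stop(sprintf("no preset script for task '%s' (valid: KATA, CPDnA)", task))
  )
}

#' @export
print.task_script <- function(x, ...) {
  cat(sprintf("Task script '%s' (%g s total)\n", x$task, x$total_duration))
  for (i in seq_along(x$labels)) {
    cat(sprintf("  %-10s %g s\n", x$labels[i], x$durations[i]))
  }
  invisible(x)
}

# Sub-task label containing time t (seconds, right-open intervals).
subtask_at <- function(script, t) {
  ends <- cumsum(script$durations)
  idx <- findInterval(t, c(0, ends), rightmost.closed = FALSE)
  idx[t >= ends[length(ends)]] <- length(script$labels)
  script$labels[pmin(idx, length(script$labels))]
}
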