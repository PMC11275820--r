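# broom-style tidiers for the package's fitted objects.

#' Tidy methods
#'
#' `tidy()` returns the object's tabular content: the loss trajectory of a
#' checkpoint (one row per pretraining step) or the per-fold accuracies of an
#' evaluation report. `glance()` returns a one-row summary.
#'
#' @param x An `eeg_checkpoint` or `eval_report`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidiers
#' @export
tidy.eeg_checkpoint <- function(x, ...) x$history

#' @rdname tidiers
#' @export
glance.eeg_checkpoint <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(steps = nrow(x$history), l_s = last$l_s, l_t = last$l_t,
                 l_total = last$l_total,
                 spatial = !is.null(x$spatial),
                 temporal = !is.null(x$temporal))
}

#' @rdname tidiers
#' @export
tidy.eval_report <- function(x, ...) x$per_fold

#' @rdname tidiers
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(folds = nrow(x$per_fold),
                 mean_accuracy = x$mean_accuracy,
                 sd_accuracy = x$sd_accuracy,
                 n = sum(x$per_fold$n_test))
}

#' Confusion matrix as a tidy tibble
#'
#' @param report An `eval_report`.
#' @return Tibble with `true`, `pred`, `n`.
#' @export
tidy_confusion <- function(report) {
  cm <- report$confusion
  tibble::tibble(
    true = rep(rownames(cm), times = ncol(cm)),
    pred = rep(colnames(cm), each = nrow(cm)),
    n = as.vector(cm))
}

#' Write an evaluation report to disk
#'
#' Stores the report as `report.json` (per-fold accuracies, summary and run
#' metadata) plus `confusion.csv`.
#'
#' @param report An `eval_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("write_eval_report() needs the jsonlite package.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(per_fold = report$per_fold,
         mean_accuracy = report$mean_accuracy,
         sd_accuracy = report$sd_accuracy,
         metadata = report$metadata),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  write.csv(report$confusion, file.path(dir, "confusion.csv"))
  invisible(dir)
}
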