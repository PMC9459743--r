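# broom-style tidiers for fitted objects and reports.

#' Tidy a trained classifier
#'
#' @param x A `tug_tcn_fit`.
#' @param ... Unused.
#' @return The epoch-by-epoch training history tibble.
#' @method tidy tug_tcn_fit
#' @export
tidy.tug_tcn_fit <- function(x, ...) {
  x$history
}

#' @rdname tidy.tug_tcn_fit
#' @return `glance()`: a one-row tibble with parameter count, epochs run,
#'   best epoch, its validation loss/accuracy and the stop reason.
#' @method glance tug_tcn_fit
#' @export
glance.tug_tcn_fit <- function(x, ...) {
  h <- x$history[x$best_epoch, ]
  tibble::tibble(
    n_parameters = count_parameters(x),
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    val_loss = h$val_loss,
    val_accuracy = h$val_acc,
    stop_reason = x$stop_reason
  )
}

#' Tidy a segmentation
#'
#' @param x A `tug_segmentation`.
#' @param fps Sampling rate used for the `time_s` column.
#' @param ... Unused.
#' @return A tibble with one row per frame: `frame`, `time_s`, `label`.
#' @method tidy tug_segmentation
#' @export
tidy.tug_segmentation <- function(x, fps = 30, ...) {
  n <- length(x$labels)
  tibble::tibble(frame = 0:(n - 1), time_s = (0:(n - 1)) / fps, label = x$labels)
}

#' @rdname tidy.tug_segmentation
#' @return `glance()`: one row with the six boundary frames, the alignment
#'   cost and score.
#' @method glance tug_segmentation
#' @export
glance.tug_segmentation <- function(x, ...) {
  b <- as.list(setNames(x$boundaries, paste0("b_", tug_event_names())))
  tibble::as_tibble(c(b, list(cost = x$cost, score = x$score,
                              n_frames = length(x$labels))))
}

#' Tidy an evaluation report
#'
#' @param x A `tug_report`.
#' @param ... Unused.
#' @return The per-subtask precision/recall/F1 tibble.
#' @method tidy tug_report
#' @export
tidy.tug_report <- function(x, ...) {
  x$class_metrics
}

#' @rdname tidy.tug_report
#' @return `glance()`: one row with overall frame accuracy, macro F1 over
#'   defined classes, and the total-TUG-time MAE in seconds.
#' @method glance tug_report
#' @export
glance.tug_report <- function(x, ...) {
  tot <- x$event_summary[x$event_summary$event == "total_tug_time", ]
  tibble::tibble(
    accuracy = x$accuracy,
    macro_f1 = mean(x$class_metrics$f1, na.rm = TRUE),
    total_tug_mae = tot$mae,
    n_trials = tot$n
  )
}
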