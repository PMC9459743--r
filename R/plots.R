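# ggplot2 visualisations for trials, training histories and segmentations.

#' Plot a trial's joint trajectories
#'
#' One panel per coordinate of each selected joint, over time.
#'
#' @param object A [tug_trial()].
#' @param joints Joints to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tug_trial
#' @export
autoplot.tug_trial <- function(object, joints = "PELVIS", ...) {
  cols <- as.vector(t(outer(joints, c("_x", "_y", "_z"), paste0)))
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "timestamp", dplyr::all_of(cols)),
    -"timestamp", names_to = "channel", values_to = "position"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$timestamp, .data$position)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "position (m)")
}

#' Plot a training history
#'
#' Training and validation loss and accuracy per epoch, with the best epoch
#' marked.
#'
#' @param object A `tug_tcn_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tug_tcn_fit
#' @export
autoplot.tug_tcn_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = c("split", "metric"), names_sep = "_",
                            values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value, colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL)
}

#' Plot a segmentation against ground truth
#'
#' Step plot of the subtask class over time; optionally overlays the
#' ground-truth labeling and the raw (pre-correction) argmax labels.
#'
#' @param object A `tug_segmentation`.
#' @param truth Optional ground-truth label vector.
#' @param raw Optional uncorrected label vector.
#' @param fps Sampling rate.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tug_segmentation
#' @export
autoplot.tug_segmentation <- function(object, truth = NULL, raw = NULL,
                                      fps = 30, ...) {
  lvl <- tug_classes()
  mk <- function(labels, which) {
    tibble::tibble(time_s = (seq_along(labels) - 1) / fps,
                   index = match(labels, lvl), series = which)
  }
  df <- mk(object$labels, "corrected")
  if (!is.null(raw)) df <- dplyr::bind_rows(df, mk(raw, "raw"))
  if (!is.null(truth)) df <- dplyr::bind_rows(df, mk(truth, "truth"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$index,
                                   colour = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(breaks = seq_along(lvl), labels = lvl) +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL)
}
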