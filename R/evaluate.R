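# Evaluation: one-vs-rest frame confusion counts, precision/recall/F1,
# frame accuracy, event-timing errors with total-TUG-time MAE, subtask
# durations/speeds, and ICC(2,1) inter-rater reliability.

#' One-vs-rest confusion counts per subtask class
#'
#' @param pred,truth Equal-length frame label vectors.
#' @param classes Classes to tabulate (default all five).
#' @return A tibble with columns `class`, `tp`, `fp`, `fn`, `tn`; each row's
#'   counts sum to the number of frames.
#' @export
frame_confusion <- function(pred, truth, classes = tug_classes()) {
  pred <- as.character(pred); truth <- as.character(truth)
  if (length(pred) != length(truth)) {
    abort("pred and truth must have equal length", class = "tug_input_error")
  }
  n <- length(pred)
  dplyr::bind_rows(lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    tibble::tibble(class = cl, tp = tp, fp = fp, fn = fn, tn = n - tp - fp - fn)
  }))
}

#' Precision, recall and F1 from confusion counts
#'
#' Precision is `TP / (TP + FP)`, recall `TP / (TP + FN)`, and F1 their
#' harmonic mean. A metric whose denominator is zero (class absent from
#' predictions and/or ground truth) is undefined and reported as `NA` with a
#' warning; such rows are excluded from macro averages downstream.
#'
#' @param counts A tibble with `tp`, `fp`, `fn` columns (e.g. from
#'   [frame_confusion()]).
#' @return The input with `precision`, `recall`, `f1` columns added.
#' @export
precision_recall_f1 <- function(counts) {
  prec <- ifelse(counts$tp + counts$fp > 0, counts$tp / (counts$tp + counts$fp), NA_real_)
  rec <- ifelse(counts$tp + counts$fn > 0, counts$tp / (counts$tp + counts$fn), NA_real_)
  if (anyNA(prec) || anyNA(rec)) {
    warn("undefined precision/recall for class(es) with empty denominator",
         class = "tug_undefined_metric")
  }
  dplyr::mutate(counts, precision = prec, recall = rec,
                f1 = f1_score(prec, rec))
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Rates in `[0, 1]`.
#' @return The F1 score `2 * precision * recall / (precision + recall)`
#'   (0 when both rates are 0).
#' @export
#' @examples
#' round(f1_score(0.955, 0.973), 3)
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
}

#' Frame classification accuracy
#'
#' Fraction of frames whose predicted class equals the ground truth; equal to
#' the micro-averaged `(TP + TN) / (TP + TN + FP + FN)` over classes.
#'
#' @param pred,truth Equal-length frame label vectors.
#' @return A fraction in `[0, 1]`.
#' @export
frame_accuracy <- function(pred, truth) {
  pred <- as.character(pred); truth <- as.character(truth)
  if (length(pred) != length(truth)) {
    abort("pred and truth must have equal length", class = "tug_input_error")
  }
  if (length(pred) == 0) abort("empty input", class = "tug_input_error")
  mean(pred == truth)
}

#' Event-timing errors for one trial
#'
#' Absolute per-event timing error plus the total-TUG-time error (the
#' difference of the StartMove-to-EndSit durations, which cancels any common
#' shift).
#'
#' @param pred,truth Complete [tug_events()] tables.
#' @return A tibble with columns `event` (the six events plus
#'   `"total_tug_time"`) and `abs_error` in seconds.
#' @export
event_errors <- function(pred, truth) {
  pt <- event_times(pred); tt <- event_times(truth)
  tibble::tibble(
    event = c(tug_event_names(), "total_tug_time"),
    abs_error = unname(c(abs(pt - tt),
                         abs(total_tug_time(pred) - total_tug_time(truth))))
  )
}

#' Aggregate event errors over trials
#'
#' @param errors A tibble of stacked [event_errors()] rows over trials.
#' @return Per-event mean absolute error and population (n) standard
#'   deviation, in seconds.
#' @export
event_error_summary <- function(errors) {
  errors |>
    dplyr::group_by(.data$event) |>
    dplyr::summarise(
      mae = mean(.data$abs_error),
      std = sqrt(mean((.data$abs_error - mean(.data$abs_error))^2)),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$event, c(tug_event_names(), "total_tug_time")))
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single rater — the standard
#' inter-rater reliability form — from the mean-squares decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#'
#' @param ratings An n x k matrix or data frame (n targets rated by k raters,
#'   n >= 3, k >= 2).
#' @return The ICC value, or `NA` with a warning when the total variance is
#'   zero.
#' @export
#' @examples
#' icc(cbind(c(1, 2, 3, 4, 5), c(1.1, 2, 2.9, 4.2, 5)))
icc <- function(ratings) {
  x <- as.matrix(ratings)
  n <- nrow(x); k <- ncol(x)
  if (n < 3 || k < 2) abort("need >= 3 targets and >= 2 raters", class = "tug_input_error")
  if (any(!is.finite(x))) abort("non-finite ratings", class = "tug_input_error")
  gm <- mean(x)
  if (all(x == x[1])) {
    warn("zero total variance: ICC undefined", class = "tug_undefined_metric")
    return(NA_real_)
  }
  rm_ <- rowMeans(x); cm <- colMeans(x)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  sse <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Subtask durations and walk speeds
#'
#' Durations derive from boundary differences; the two walk segments also get
#' a mean speed of `walk_distance / duration`.
#'
#' @param boundaries A `tug_segmentation` or six 0-based boundary frames.
#' @param fps Sampling rate.
#' @param walk_distance Walk path length in meters.
#' @param n_frames Total recording length in frames; required (or taken from
#'   the segmentation) to report the lead/trail sit durations.
#' @return A tibble `subtask`, `duration` (s), `speed` (m/s, walks only).
#' @export
subtask_durations <- function(boundaries, fps = 30, walk_distance = 3,
                              n_frames = NULL) {
  if (inherits(boundaries, "tug_segmentation")) {
    n_frames <- n_frames %||% length(boundaries$labels)
    boundaries <- boundaries$boundaries
  }
  if (is.null(n_frames)) abort("n_frames required", class = "tug_input_error")
  edges <- c(0, boundaries, n_frames)
  durations <- diff(edges) / fps
  subtask <- c("lead_sit", "sit_to_stand", "walk", "turn", "walk_back",
               "stand_to_sit", "trail_sit")
  tibble::tibble(
    subtask = subtask,
    duration = durations,
    speed = ifelse(subtask %in% c("walk", "walk_back"),
                   walk_distance / durations, NA_real_)
  )
}

#' Build a segmentation report over a set of trials
#'
#' Pools frames across trials for the per-subtask precision/recall/F1 table
#' and overall accuracy, and aggregates per-event and total-TUG-time errors.
#'
#' @param results A tibble with list-columns `pred_labels`, `truth_labels`
#'   (frame label vectors) and `pred_events`, `truth_events`
#'   ([tug_events()] tables).
#' @return A `tug_report`: list with `class_metrics`, `accuracy`,
#'   `per_trial_accuracy`, `event_summary` tibbles.
#' @export
segmentation_report <- function(results) {
  pred <- unlist(results$pred_labels, use.names = FALSE)
  truth <- unlist(results$truth_labels, use.names = FALSE)
  cm <- precision_recall_f1(frame_confusion(pred, truth))
  per_trial <- purrr::map2_dbl(results$pred_labels, results$truth_labels,
                               frame_accuracy)
  errs <- dplyr::bind_rows(
    purrr::map2(results$pred_events, results$truth_events, event_errors)
  )
  structure(
    list(class_metrics = cm,
         accuracy = frame_accuracy(pred, truth),
         per_trial_accuracy = tibble::tibble(
           trial = seq_along(per_trial), accuracy = per_trial),
         event_summary = event_error_summary(errs)),
    class = "tug_report"
  )
}

#' @export
print.tug_report <- function(x, ...) {
  cat(sprintf("<tug_report> overall frame accuracy %.3f\n", x$accuracy))
  print(x$class_metrics)
  print(x$event_summary)
  invisible(x)
}
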