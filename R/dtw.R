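# Order-constrained label correction: optimal monotone alignment of the
# per-frame class scores to the canonical 7-slot TUG template
# (sit, sit-to-stand, walk, turn, walk back, stand-to-sit, sit), the
# dynamic-time-warping reading of snapping a prediction sequence onto the
# strict subtask order. Local cost is 1 - p(slot class); leading/trailing sit
# may be empty, the five active segments may not. Fragmentation errors
# (spurious short runs of a wrong class inside a segment) are removed by
# construction; boundary shift errors are not correctable by order alone.

# probabilities or hard labels -> T x 5 probability matrix in class order
as_prob_matrix <- function(x) {
  cls <- tug_classes()
  if (is.character(x) || is.factor(x)) {
    y <- match(as.character(x), cls)
    if (anyNA(y)) abort("unknown class label", class = "tug_input_error")
    p <- matrix(0, length(y), length(cls), dimnames = list(NULL, cls))
    p[cbind(seq_along(y), y)] <- 1
    return(p)
  }
  p <- as.matrix(x)
  if (ncol(p) != length(cls)) {
    abort("probability matrix must have 5 class columns", class = "tug_input_error")
  }
  if (!is.null(colnames(p))) {
    if (!setequal(colnames(p), cls)) {
      abort("probability columns must be the 5 TUG classes", class = "tug_input_error")
    }
    p <- p[, cls, drop = FALSE]
  }
  if (any(!is.finite(p)) || any(p < 0)) {
    abort("invalid probability rows", class = "tug_input_error")
  }
  p
}

#' Correct frame labels against the canonical subtask order
#'
#' Finds, by dynamic programming, the template-ordered frame labeling that
#' maximizes the total probability assigned to each frame's slot class
#' (equivalently minimizes the total `1 - p` cost) over all monotone
#' frame-to-slot assignments. Among cost ties the earliest feasible
#' boundaries are chosen, making the result deterministic.
#'
#' @param frame_probs A T x 5 probability matrix (columns named with
#'   [tug_classes()]), or a length-T vector of hard class labels (treated as
#'   one-hot).
#' @return A `tug_segmentation` list: `labels` (length-T corrected class
#'   vector), `boundaries` (six 0-based frame indices, the first frame of
#'   each template slot after the leading sit), `cost` (total `1 - p`) and
#'   `score` (total assigned probability, `T - cost`).
#' @export
#' @examples
#' seg <- dtw_correct(c("sit", "sit_to_stand", "walk", "stand_to_sit",
#'                      "walk", "turn", "walk", "stand_to_sit", "sit"))
#' seg$labels
dtw_correct <- function(frame_probs) {
  p <- as_prob_matrix(frame_probs)
  T0 <- nrow(p)
  if (T0 < 5) {
    abort("need at least 5 frames to host the active segments",
          class = "tug_input_error")
  }
  tmpl <- match(tug_template(), tug_classes())
  # CC[e, j]: cost of assigning frames 1..e-1 to slot j's class, cumulative
  C <- 1 - p[, tmpl, drop = FALSE]
  CC <- rbind(0, apply(C, 2, cumsum))
  # H[[j]][t]: minimal cost of frames t..T over slots j..7
  H <- vector("list", 7)
  H[[7]] <- CC[T0 + 1, 7] - CC[, 7]
  for (j in 6:2) {
    M <- CC[, j] + H[[j + 1]]
    SM <- rev(cummin(rev(M)))          # suffix minimum over end positions
    H[[j]] <- c(-CC[seq_len(T0), j] + SM[-1], Inf)  # end must exceed start
  }
  opt <- min(CC[, 1] + H[[2]])
  tol <- 1e-9 * max(1, abs(opt))
  # earliest-boundary reconstruction: fix each slot end greedily
  bounds <- integer(6)
  pos <- 1L
  acc <- 0
  for (j in 1:6) {
    lo <- if (j == 1) pos else pos + 1L
    e_range <- lo:(T0 + 1)
    cand <- acc + (CC[e_range, j] - CC[pos, j]) + H[[j + 1]][e_range]
    e <- e_range[which(cand <= opt + tol)[1]]
    bounds[j] <- e
    acc <- acc + CC[e, j] - CC[pos, j]
    pos <- e
  }
  slot <- findInterval(seq_len(T0), bounds) + 1L
  structure(
    list(labels = tug_template()[slot], boundaries = bounds - 1L,
         cost = opt, score = T0 - opt),
    class = "tug_segmentation"
  )
}

#' @export
print.tug_segmentation <- function(x, ...) {
  cat(sprintf("<tug_segmentation> %d frames | boundaries %s | score %.3f\n",
              length(x$labels), paste(x$boundaries, collapse = ","), x$score))
  invisible(x)
}

#' Extract the six TUG events from segment boundaries
#'
#' Each event is the first frame of the segment it opens: StartMove the first
#' sit-to-stand frame, StartWalk the first walk frame, StartTurn the first
#' turn frame, EndTurn the first walk-back frame, StartSit the first
#' stand-to-sit frame and EndSit the first trailing-sit frame. Times are
#' 0-based frame indices over the sampling rate.
#'
#' @param boundaries A `tug_segmentation` or its six 0-based boundary frame
#'   indices.
#' @param fps Sampling rate in frames per second.
#' @return A [tug_events()] tibble.
#' @export
#' @examples
#' extract_events(c(60, 90, 180, 210, 300, 330), fps = 30)$time_s
extract_events <- function(boundaries, fps = 30) {
  if (inherits(boundaries, "tug_segmentation")) boundaries <- boundaries$boundaries
  if (length(boundaries) != 6 || any(diff(boundaries) <= 0)) {
    abort("six strictly increasing boundary frames required",
          class = "tug_contract_error")
  }
  tug_events(boundaries / fps)
}

#' Total TUG time from a six-event table
#'
#' The elapsed time between the first (StartMove) and last (EndSit) events.
#'
#' @param events A [tug_events()] tibble.
#' @return Seconds.
#' @export
total_tug_time <- function(events) {
  t <- event_times(events)
  unname(t["EndSit"] - t["StartMove"])
}
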