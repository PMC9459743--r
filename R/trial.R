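# TrialRecording container: a tibble of per-frame joint positions with
# subject/group/fps metadata held in attributes.

#' Construct a TUG trial recording
#'
#' A trial recording is a tibble with one row per frame: a 0-based `frame`
#' column, a `timestamp` column in seconds from the first frame, and three
#' columns `<JOINT>_x`, `<JOINT>_y`, `<JOINT>_z` per tracked joint (positions
#' in meters, camera or aligned frame; `y` is vertical). Subject id, group and
#' sampling rate ride along as attributes.
#'
#' @param positions A data frame with columns `frame`, `timestamp` and
#'   `<JOINT>_{x,y,z}` triples for a subset of [azure_kinect_joints()].
#' @param subject_id Opaque subject identifier.
#' @param group One of `"healthy_young"`, `"older_adult"`, `"stroke"`, or `NA`.
#' @param fps Sampling rate in frames per second; inferred from the median
#'   timestamp spacing when `NULL`.
#' @return A `tug_trial` tibble.
#' @export
tug_trial <- function(positions, subject_id = "S0", group = NA_character_,
                      fps = NULL) {
  x <- tibble::as_tibble(positions)
  if ("frame" %in% names(x)) x$frame <- as.integer(x$frame)
  if (is.null(fps)) {
    dt <- diff(x$timestamp)
    fps <- 1 / stats::median(dt)
    # snap to an integer rate when within rounding slack of one
    if (abs(fps - round(fps)) < 1e-6 * max(1, round(fps))) fps <- round(fps)
  }
  attr(x, "subject_id") <- subject_id
  attr(x, "group") <- group
  attr(x, "fps") <- fps
  class(x) <- c("tug_trial", class(tibble::tibble()))
  validate_tug_trial(x)
}

#' @rdname tug_trial
#' @param x A `tug_trial` object.
#' @export
validate_tug_trial <- function(x) {
  if (!all(c("frame", "timestamp") %in% names(x))) {
    abort("trial must have `frame` and `timestamp` columns", class = "tug_format_error")
  }
  if (nrow(x) < 2) {
    abort("trial must have at least 2 frames", class = "tug_validation_error")
  }
  if (any(diff(x$timestamp) <= 0)) {
    abort("timestamps must be strictly increasing", class = "tug_validation_error")
  }
  jc <- setdiff(names(x), c("frame", "timestamp"))
  m <- regmatches(jc, regexec("^(.*)_([xyz])$", jc))
  bad <- jc[vapply(m, length, 1L) != 3]
  if (length(bad) > 0) {
    abort(paste0("unrecognised columns: ", paste(bad, collapse = ", ")),
          class = "tug_format_error")
  }
  joints <- unique(vapply(m, `[`, "", 2))
  unknown <- setdiff(joints, azure_kinect_joints())
  if (length(unknown) > 0) {
    abort(paste0("unknown joints: ", paste(unknown, collapse = ", ")),
          class = "tug_format_error")
  }
  if (length(joints) > 32) abort("more than 32 joints", class = "tug_validation_error")
  for (j in joints) {
    need <- paste0(j, "_", c("x", "y", "z"))
    if (!all(need %in% names(x))) {
      abort(paste0("joint ", j, " is missing one of its x/y/z columns"),
            class = "tug_format_error")
    }
  }
  pos <- as.matrix(x[jc])
  if (!all(is.finite(pos))) {
    abort("non-finite joint positions", class = "tug_validation_error")
  }
  x
}

#' @export
print.tug_trial <- function(x, ...) {
  cat(sprintf(
    "<tug_trial> subject=%s group=%s fps=%g frames=%d joints=%d\n",
    trial_subject(x), trial_group(x), trial_fps(x), nrow(x),
    length(trial_joints(x))
  ))
  NextMethod()
}

#' Trial metadata accessors
#'
#' @param x A `tug_trial`.
#' @return `trial_fps()` the sampling rate; `trial_subject()` and
#'   `trial_group()` the metadata strings; `trial_joints()` the tracked joint
#'   names; `trial_duration()` the recording length in seconds.
#' @export
trial_fps <- function(x) attr(x, "fps")

#' @rdname trial_fps
#' @export
trial_subject <- function(x) attr(x, "subject_id")

#' @rdname trial_fps
#' @export
trial_group <- function(x) attr(x, "group")

#' @rdname trial_fps
#' @export
trial_joints <- function(x) {
  jc <- setdiff(names(x), c("frame", "timestamp"))
  unique(sub("_[xyz]$", "", jc))
}

#' @rdname trial_fps
#' @export
trial_duration <- function(x) {
  x$timestamp[nrow(x)] - x$timestamp[1] + 1 / trial_fps(x)
}

#' Extract a joint-feature matrix from a trial
#'
#' Selects the x/y/z coordinate columns of the requested joints, joint-major
#' (all three coordinates of the first joint, then the second, ...), as the
#' numeric T x 3k matrix fed to the classifier.
#'
#' @param recording A `tug_trial`.
#' @param joints Character vector of joint names, e.g. `"PELVIS"` or
#'   `c("PELVIS", "HEAD")`. Must be non-empty and present in the recording.
#' @return A numeric matrix with `nrow(recording)` rows and `3 * length(joints)`
#'   columns named `<JOINT>_{x,y,z}`.
#' @export
#' @examples
#' tr <- simulate_tug(1, seed = 1)$trial[[1]]
#' dim(select_features(tr, "PELVIS"))
select_features <- function(recording, joints) {
  if (length(joints) == 0) {
    abort("empty joint selection", class = "tug_lookup_error")
  }
  missing <- setdiff(joints, trial_joints(recording))
  if (length(missing) > 0) {
    abort(paste0("joints not in recording: ", paste(missing, collapse = ", ")),
          class = "tug_lookup_error")
  }
  cols <- as.vector(t(outer(joints, c("_x", "_y", "_z"), paste0)))
  m <- as.matrix(recording[cols])
  rownames(m) <- NULL
  m
}

#' Construct a six-event table
#'
#' @param times Named or unnamed numeric vector of the six event times in
#'   seconds from recording start, in the order of [tug_event_names()];
#'   must be strictly increasing.
#' @return A `tug_events` tibble with columns `event`, `label` (0-5) and
#'   `time_s`.
#' @export
tug_events <- function(times) {
  times <- unname(times)
  if (length(times) != 6 || any(!is.finite(times))) {
    abort("exactly six finite event times required", class = "tug_validation_error")
  }
  if (any(diff(times) <= 0)) {
    abort("event times must be strictly increasing", class = "tug_validation_error")
  }
  x <- tibble::tibble(event = tug_event_names(), label = 0:5, time_s = times)
  class(x) <- c("tug_events", class(x))
  x
}

# numeric vector of the six times, named
event_times <- function(events) {
  setNames(events$time_s, events$event)
}
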