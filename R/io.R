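# On-disk formats: wide skeleton CSV (one row per frame) and a JSON mirror of
# the Azure Kinect body-tracking export; event-label sidecar CSV.

#' Read a skeleton trajectory recording
#'
#' The CSV dialect is wide, one row per frame, with header
#' `frame,timestamp,<JOINT>_x,<JOINT>_y,<JOINT>_z,...`; joint names must be
#' Azure Kinect body-tracking joints. The JSON format mirrors the body-tracking
#' export: a top-level object with `subject_id`, `group`, `fps` and a `frames`
#' array of `{frame, timestamp, joints: {<JOINT>: [x, y, z]}}` records.
#' The sampling rate is inferred from the timestamp spacing.
#'
#' @param path File to read.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @param subject_id,group Metadata to attach (CSV carries none itself).
#' @return A validated [tug_trial()].
#' @export
read_trial <- function(path, format = c("auto", "csv", "json"),
                       subject_id = NULL, group = NA_character_) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "tug_io_error")
  if (format == "csv") {
    # base read.csv: strtod parsing is correctly rounded, so write/read
    # round-trips doubles bit-exactly
    x <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
    if (!all(c("frame", "timestamp") %in% names(x))) {
      abort("skeleton CSV must start with `frame,timestamp`", class = "tug_format_error")
    }
    tug_trial(x, subject_id = subject_id %||% basename(path), group = group)
  } else {
    j <- jsonlite::read_json(path, simplifyVector = FALSE)
    frames <- j$frames
    if (is.null(frames) || length(frames) == 0) {
      abort("JSON recording has no frames", class = "tug_format_error")
    }
    joints <- names(frames[[1]]$joints)
    rows <- purrr::map(frames, function(fr) {
      vals <- unlist(fr$joints[joints], use.names = FALSE)
      c(frame = fr$frame, timestamp = fr$timestamp, vals)
    })
    m <- do.call(rbind, rows)
    colnames(m) <- c("frame", "timestamp",
                     as.vector(t(outer(joints, c("_x", "_y", "_z"), paste0))))
    tug_trial(tibble::as_tibble(m),
              subject_id = subject_id %||% j$subject_id %||% basename(path),
              group = if (!is.na(group) || is.null(j$group)) group else j$group,
              fps = j$fps)
  }
}

#' Write a skeleton trajectory recording
#'
#' Emits the wide CSV dialect (see [read_trial()]) or its JSON mirror.
#' Round-trips losslessly at full double precision.
#'
#' @param recording A valid [tug_trial()].
#' @param path Output file.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_trial <- function(recording, path, format = c("auto", "csv", "json")) {
  recording <- validate_tug_trial(recording)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- as.data.frame(recording)
    # full precision so read(write(x)) is bit-equal
    num <- vapply(df, is.double, TRUE)
    df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
    tryCatch(
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
      error = function(e) abort(conditionMessage(e), class = "tug_io_error")
    )
  } else {
    joints <- trial_joints(recording)
    frames <- purrr::pmap(as.list(recording), function(...) {
      r <- list(...)
      jl <- lapply(joints, function(j) unlist(r[paste0(j, "_", c("x", "y", "z"))],
                                              use.names = FALSE))
      list(frame = r$frame, timestamp = r$timestamp, joints = setNames(jl, joints))
    })
    obj <- list(subject_id = trial_subject(recording),
                group = trial_group(recording), fps = trial_fps(recording),
                frames = frames)
    tryCatch(
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA),
      error = function(e) abort(conditionMessage(e), class = "tug_io_error")
    )
  }
  invisible(path)
}

#' Read and write event-label sidecar files
#'
#' Sidecar CSV with header `event,label,time_s` and one row per TUG event
#' (labels 0-5 in the order of [tug_event_names()]).
#'
#' @param path Sidecar file path.
#' @return `read_events()` a [tug_events()] tibble; `write_events()` the path,
#'   invisibly.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "tug_io_error")
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("event", "label", "time_s") %in% names(x))) {
    abort("event sidecar must have columns event,label,time_s",
          class = "tug_format_error")
  }
  x <- x[match(tug_event_names(), x$event), ]
  if (any(is.na(x$event))) {
    abort("event sidecar missing one of the six TUG events", class = "tug_format_error")
  }
  tug_events(x$time_s)
}

#' @rdname read_events
#' @param events A [tug_events()] tibble.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "tug_events"))
  readr::write_csv(as.data.frame(events), path, progress = FALSE)
  invisible(path)
}
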