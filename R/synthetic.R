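# Synthetic TUG trial simulator. Emulates the recording protocol: a subject
# sits on a chair, rises, walks 3 m to a cone, turns, walks back, sits down,
# with one second of seated padding at both ends and 30 Hz skeleton sampling.
# Kinematic primitives are minimum-jerk displacement profiles per phase and a
# sinusoidal trunk-pitch sweep through the transitions; the trunk pitch crosses
# 45 degrees exactly at the StartMove and EndSit ground-truth instants,
# matching the expert labeling criterion for those events.

# minimum-jerk position profile on [0, 1]
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Group presets for the TUG simulator
#'
#' Total-duration means are the cohort averages reported for the protocol
#' (healthy young 11.34 s, older adults 15.33 s, stroke 43.11 s). The standard
#' deviations, phase fractions, chair geometry and noise level are package
#' defaults, not study values: per-subtask duration statistics were never
#' published.
#'
#' @param group `"healthy_young"`, `"older_adult"` or `"stroke"`.
#' @param total_mean,total_sd Mean and SD (seconds) of the total recording
#'   duration (including the two 1 s seated pads), drawn truncated-normal.
#' @param fractions Length-5 positive vector summing to 1: share of the active
#'   (non-pad) duration given to sit-to-stand, walk, turn, walk back,
#'   stand-to-sit.
#' @param walk_distance Chair-to-cone distance in meters.
#' @param seat_height Chair seat height in meters (pelvis sits 5 cm above).
#' @param noise_sd Gaussian measurement noise SD on each joint coordinate (m).
#' @param lead_sit,trail_sit Seated padding durations in seconds.
#' @return A `tug_preset` list.
#' @export
#' @examples
#' group_preset("stroke")$total_mean
group_preset <- function(group = c("older_adult", "healthy_young", "stroke"),
                         total_mean = NULL, total_sd = NULL,
                         fractions = c(0.15, 0.30, 0.10, 0.30, 0.15),
                         walk_distance = 3, seat_height = 0.45,
                         noise_sd = 0.005, lead_sit = 1, trail_sit = 1) {
  group <- match.arg(group)
  defaults <- list(
    healthy_young = c(11.34, 1.2),
    older_adult   = c(15.33, 1.8),
    stroke        = c(43.11, 6.0)
  )[[group]]
  total_mean <- total_mean %||% defaults[1]
  total_sd <- total_sd %||% defaults[2]
  if (total_sd < 0) abort("total_sd must be >= 0", class = "tug_parameter_error")
  if (length(fractions) != 5 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    abort("fractions must be 5 positive values summing to 1",
          class = "tug_parameter_error")
  }
  if (walk_distance <= 0) abort("walk_distance must be > 0", class = "tug_parameter_error")
  structure(
    list(group = group, total_mean = total_mean, total_sd = total_sd,
         fractions = fractions, walk_distance = walk_distance,
         seat_height = seat_height, noise_sd = noise_sd,
         lead_sit = lead_sit, trail_sit = trail_sit),
    class = "tug_preset"
  )
}

#' Draw a phase plan for one trial
#'
#' The total duration is drawn from a normal truncated below at
#' `lead_sit + trail_sit + 2` seconds; the five active-phase durations are the
#' preset's fractions of the remaining (non-pad) time.
#'
#' @param preset A [group_preset()].
#' @param seed Integer seed for the draw.
#' @return A `tug_phase_plan` tibble with columns `phase` and `duration`
#'   (seconds), seven rows in canonical order.
#' @export
sample_phase_plan <- function(preset, seed = 1) {
  stopifnot(inherits(preset, "tug_preset"))
  pad <- preset$lead_sit + preset$trail_sit
  lower <- pad + 2
  if (preset$total_sd == 0) {
    total <- preset$total_mean
    if (total <= lower) {
      abort("degenerate preset: total duration below minimum",
            class = "tug_parameter_error")
    }
  } else {
    set.seed(seed)
    repeat {
      total <- stats::rnorm(1, preset$total_mean, preset$total_sd)
      if (total > lower) break
    }
  }
  active <- total - pad
  x <- tibble::tibble(
    phase = c("lead_sit", "sit_to_stand", "walk_out", "turn", "walk_back",
              "stand_to_sit", "trail_sit"),
    duration = c(preset$lead_sit, preset$fractions * active, preset$trail_sit)
  )
  class(x) <- c("tug_phase_plan", class(x))
  x
}

#' Synthesize one labeled TUG trial
#'
#' Generates pelvis, spine chest, head, hand and ankle trajectories following
#' the phase plan, in a camera frame rotated by a (by default random) azimuth
#' about the vertical so that downstream axis alignment is exercised, adds
#' Gaussian position noise, and returns the recording together with
#' ground-truth frame labels and event times. Labels and events come from the
#' plan's phase boundaries, never from the noisy signal.
#'
#' @param plan A [sample_phase_plan()] result.
#' @param preset The [group_preset()] the plan was drawn from.
#' @param seed Integer seed for azimuth, placement and noise.
#' @param fps Sampling rate, frames per second.
#' @param azimuth Camera-frame walking azimuth in radians; random if `NULL`.
#' @param origin Length-2 horizontal camera offset (m); random if `NULL`.
#' @param subject_id Subject identifier stored on the trial.
#' @return A list with elements `trial` ([tug_trial()]), `labels` (tibble
#'   `frame`, `label`), `events` ([tug_events()]) and `plan`.
#' @export
synthesize_trial <- function(plan, preset, seed = 1, fps = 30,
                             azimuth = NULL, origin = NULL,
                             subject_id = "S0") {
  stopifnot(inherits(plan, "tug_phase_plan"), inherits(preset, "tug_preset"))
  d <- plan$duration
  if (any(d <= 0)) abort("all phase durations must be > 0", class = "tug_parameter_error")
  cb <- cumsum(d)                      # phase end times; cb[1:6] are the events
  total <- cb[7]
  n <- round(fps * total)
  t <- (0:(n - 1)) / fps
  phase <- findInterval(t, cb[1:6]) + 1L
  tau <- (t - c(0, cb)[phase]) / d[phase]

  set.seed(seed)
  azimuth <- azimuth %||% stats::runif(1, 0, 2 * pi)
  origin <- origin %||% stats::runif(2, -1, 1)

  seat <- preset$seat_height + 0.05
  stand <- 0.95
  D <- preset$walk_distance
  step_in <- 0.10                      # forward pelvis shift while rising

  # pelvis, local frame: x walking axis (chair -> cone positive), y vertical
  px <- numeric(n); py <- numeric(n); pz <- numeric(n)
  px[phase == 2] <- step_in * min_jerk(tau[phase == 2])
  px[phase == 3] <- step_in + (D - step_in) * min_jerk(tau[phase == 3])
  px[phase == 4] <- D
  px[phase == 5] <- D - (D - step_in) * min_jerk(tau[phase == 5])
  px[phase == 6] <- step_in * (1 - min_jerk(tau[phase == 6]))
  py[] <- seat
  py[phase == 2] <- seat + (stand - seat) * min_jerk(tau[phase == 2])
  py[phase %in% 3:5] <- stand
  py[phase == 6] <- stand - (stand - seat) * min_jerk(tau[phase == 6])
  gait <- phase %in% c(3, 5)
  py[gait] <- py[gait] + 0.015 * sin(2 * pi * 1.8 * t[gait])
  pz[phase == 4] <- 0.12 * sin(pi * tau[phase == 4])

  # heading azimuth (0 outbound, pi after the turn)
  hd <- ifelse(phase <= 3, 0, ifelse(phase == 4, pi * min_jerk(tau), pi))

  # trunk pitch (deg from vertical); crosses 45 exactly at StartMove/EndSit
  pitch <- numeric(n)
  r1 <- min(0.4, 0.5 * d[1]); r7 <- min(0.4, 0.5 * d[7])
  i <- phase == 1
  pitch[i] <- 45 * min_jerk((t[i] - (cb[1] - r1)) / r1)
  i <- phase == 2
  pitch[i] <- ifelse(tau[i] < 0.3,
                     45 + 15 * min_jerk(tau[i] / 0.3),
                     60 - 55 * min_jerk((tau[i] - 0.3) / 0.7))
  pitch[phase %in% 3:5] <- 5
  i <- phase == 6
  pitch[i] <- ifelse(tau[i] < 0.7,
                     5 + 55 * min_jerk(tau[i] / 0.7),
                     60 - 15 * min_jerk((tau[i] - 0.7) / 0.3))
  i <- phase == 7
  pitch[i] <- 45 * (1 - min_jerk((t[i] - cb[6]) / r7))
  th <- pitch * pi / 180

  hx <- cos(hd); hz <- sin(hd)         # heading unit vector, horizontal
  lx <- -sin(hd); lz <- cos(hd)        # lateral (left) unit vector

  trunk_dir <- function(len) {
    cbind(px + len * sin(th) * hx, py + len * cos(th), pz + len * sin(th) * hz)
  }
  limb <- function(side, lateral, swing_amp, swing_hz, swing_ph, y0, bounce) {
    sw <- numeric(n)
    sw[gait] <- swing_amp * sin(2 * pi * swing_hz * t[gait] + swing_ph)
    y <- y0 + bounce * pmax(0, side * sin(2 * pi * 1.8 * t)) * gait
    cbind(px + side * lateral * lx + sw * hx,
          y,
          pz + side * lateral * lz + sw * hz)
  }
  joints <- list(
    PELVIS      = cbind(px, py, pz),
    SPINE_CHEST = trunk_dir(0.25),
    HEAD        = trunk_dir(0.55),
    HAND_LEFT   = limb(+1, 0.18, 0.22, 0.9, 0, NA, 0) ,
    HAND_RIGHT  = limb(-1, 0.18, 0.22, 0.9, pi, NA, 0),
    ANKLE_LEFT  = limb(+1, 0.10, 0.25, 1.8, 0, 0.10, 0.05),
    ANKLE_RIGHT = limb(-1, 0.10, 0.25, 1.8, pi, 0.10, 0.05)
  )
  joints$HAND_LEFT[, 2] <- py - 0.10
  joints$HAND_RIGHT[, 2] <- py - 0.10

  ca <- cos(azimuth); sa <- sin(azimuth)
  cols <- list(frame = 0:(n - 1), timestamp = t)
  for (j in names(joints)) {
    p <- joints[[j]]
    xc <- ca * p[, 1] - sa * p[, 3] + origin[1]
    zc <- sa * p[, 1] + ca * p[, 3] + origin[2]
    yc <- p[, 2]
    if (preset$noise_sd > 0) {
      xc <- xc + stats::rnorm(n, 0, preset$noise_sd)
      yc <- yc + stats::rnorm(n, 0, preset$noise_sd)
      zc <- zc + stats::rnorm(n, 0, preset$noise_sd)
    }
    cols[[paste0(j, "_x")]] <- xc
    cols[[paste0(j, "_y")]] <- yc
    cols[[paste0(j, "_z")]] <- zc
  }
  trial <- tug_trial(tibble::as_tibble(cols), subject_id = subject_id,
                     group = preset$group, fps = fps)
  labels <- tibble::tibble(
    frame = 0:(n - 1),
    label = tug_template()[phase]
  )
  list(trial = trial, labels = labels, events = tug_events(cb[1:6]), plan = plan)
}

#' Generate a batch of labeled synthetic TUG trials
#'
#' Per-trial seeds derive deterministically from `seed`, so the same call
#' reproduces the same dataset exactly.
#'
#' @param n Number of trials.
#' @param groups Group name(s), recycled to length `n`.
#' @param seed Master integer seed.
#' @param presets Optional named list of [group_preset()]s overriding the
#'   defaults per group.
#' @param fps Sampling rate.
#' @return A nested tibble with one row per trial: `trial_id`, `subject`,
#'   `group`, and list-columns `trial`, `labels`, `events`, `plan`.
#' @export
#' @examples
#' ds <- simulate_tug(3, groups = c("older_adult", "stroke"), seed = 7)
#' ds$group
simulate_tug <- function(n, groups = "older_adult", seed = 1,
                         presets = NULL, fps = 30) {
  stopifnot(n >= 1)
  groups <- rep_len(groups, n)
  set.seed(seed)
  plan_seeds <- sample.int(.Machine$integer.max, n)
  trial_seeds <- sample.int(.Machine$integer.max, n)
  rows <- purrr::map(seq_len(n), function(i) {
    preset <- presets[[groups[i]]] %||% group_preset(groups[i])
    plan <- sample_phase_plan(preset, seed = plan_seeds[i])
    sim <- synthesize_trial(plan, preset, seed = trial_seeds[i], fps = fps,
                            subject_id = sprintf("S%03d", i))
    tibble::tibble(
      trial_id = i, subject = sprintf("S%03d", i), group = groups[i],
      trial = list(sim$trial), labels = list(sim$labels),
      events = list(sim$events), plan = list(sim$plan)
    )
  })
  dplyr::bind_rows(rows)
}
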