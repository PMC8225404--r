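# Movement-initiation event detection and pruning.
#
# An event is a rest -> move transition preceded by at least 0.5 s of
# contiguous rest and followed by at least 0.5 s of contiguous move. Events
# are annotated with reach kinematics and then pruned: duration in [0.5, 4] s
# (closed interval), mean tracking confidence > 0.4, quadratic radial fit
# R^2 > 0.6, and per day at most the 200 events with the highest onset
# speeds (ties broken by earlier onset).

#' Detect movement-initiation onsets
#'
#' @param states a [state_sequence()].
#' @param frame_rate frames per second; 0.5 s must be an integral number of
#'   frames (15 at 30 fps).
#' @param day recording day index attached to each event.
#' @param day_start_time clock time (s of day) of the first frame.
#' @return data.frame of events (possibly zero rows) with columns
#'   `onset_frame` (1-based index of the first move frame), `onset_time` (s),
#'   `day`, `clock_time` (s of day), `duration` (s, length of the move dwell
#'   containing the onset), and `move_end_frame`.
#' @export
detect_onsets <- function(states, frame_rate, day = 1L, day_start_time = 0) {
  stopifnot(inherits(states, "state_sequence"))
  win <- 0.5 * frame_rate
  if (abs(win - round(win)) > 1e-9)
    stop("0.5 s must be an integral number of frames at this frame rate")
  win <- as.integer(round(win))
  lab <- states$labels
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- list()
  for (i in seq_along(runs$values)) {
    if (runs$values[i] != "move" || i == 1) next
    if (runs$values[i - 1] != "rest") next
    if (runs$lengths[i - 1] < win || runs$lengths[i] < win) next
    onset <- starts[i]
    out[[length(out) + 1]] <- data.frame(
      onset_frame = onset,
      onset_time = (onset - 1) / frame_rate,
      day = day,
      clock_time = (day_start_time + (onset - 1) / frame_rate) %% 86400,
      duration = runs$lengths[i] / frame_rate,
      move_end_frame = ends[i])
  }
  if (length(out) == 0)
    return(data.frame(onset_frame = integer(0), onset_time = numeric(0),
                      day = integer(0), clock_time = numeric(0),
                      duration = numeric(0), move_end_frame = integer(0)))
  do.call(rbind, out)
}

# Radial displacement from the onset position over a frame range.
radial_displacement <- function(traj, onset_frame, frames) {
  sqrt((traj$x[frames] - traj$x[onset_frame])^2 +
       (traj$y[frames] - traj$y[onset_frame])^2)
}

#' Coefficient of determination of a quadratic fit to radial movement
#'
#' Degree-2 polynomial fit of the wrist's radial displacement (relative to
#' its position at movement initiation) against time over the move dwell.
#' Movements with a single smooth out-and-back excursion score near 1.
#'
#' @param traj a [wrist_trajectory()].
#' @param event one event row from [detect_onsets()].
#' @return R^2 in (-Inf, 1]; NA (with a warning) if the dwell has fewer than
#'   3 frames.
#' @export
quad_fit_r2 <- function(traj, event) {
  frames <- event$onset_frame:event$move_end_frame
  if (length(frames) < 3) {
    warning("move dwell shorter than 3 frames; quadratic fit undefined")
    return(NA_real_)
  }
  r <- radial_displacement(traj, event$onset_frame, frames)
  t <- (frames - frames[1]) / traj$frame_rate
  fit <- stats::lm.fit(cbind(1, t, t^2), r)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((r - mean(r))^2)
  if (ss_tot < 1e-300) return(1)          # constant radial trace: perfect fit
  1 - ss_res / ss_tot
}

#' Annotate detected events with reach kinematics
#'
#' Adds reach magnitude (maximum radial displacement over the move dwell),
#' raw and vertically-folded reach angle (pixel y grows downward, so "up"
#' means decreasing y), onset speed (mean radial speed over the first 0.5 s
#' of the move dwell), mean tracking confidence over the dwell, and the
#' quadratic-fit R^2.
#'
#' @param events data.frame from [detect_onsets()].
#' @param traj the [wrist_trajectory()] the states were decoded from.
#' @return events with columns `reach_magnitude`, `reach_angle_raw`,
#'   `reach_angle`, `onset_speed`, `mean_confidence`, `quad_r2` added.
#' @export
annotate_events <- function(events, traj) {
  n <- nrow(events)
  add <- data.frame(reach_magnitude = numeric(n), reach_angle_raw = numeric(n),
                    reach_angle = numeric(n), onset_speed = numeric(n),
                    mean_confidence = numeric(n), quad_r2 = numeric(n))
  win <- as.integer(round(0.5 * traj$frame_rate))
  for (i in seq_len(n)) {
    ev <- events[i, ]
    frames <- ev$onset_frame:ev$move_end_frame
    r <- radial_displacement(traj, ev$onset_frame, frames)
    k <- which.max(r)
    add$reach_magnitude[i] <- r[k]
    dx <- traj$x[frames[k]] - traj$x[ev$onset_frame]
    dy <- traj$y[frames[k]] - traj$y[ev$onset_frame]
    ang <- atan2(-dy, dx) * 180 / pi       # -dy: up = decreasing y
    add$reach_angle_raw[i] <- ang %% 360
    add$reach_angle[i] <- transform_angle(ang %% 360)
    onset_win <- frames[seq_len(min(win, length(frames)))]
    ro <- radial_displacement(traj, ev$onset_frame, onset_win)
    add$onset_speed[i] <- mean(abs(diff(ro))) * traj$frame_rate
    add$mean_confidence[i] <- mean(traj$confidence[frames])
    add$quad_r2[i] <- suppressWarnings(quad_fit_r2(traj, ev))
  }
  cbind(events, add)
}

#' Prune annotated events
#'
#' Keeps events with duration in the closed interval [0.5, 4] s, mean
#' tracking confidence > 0.4 and quadratic-fit R^2 > 0.6, then keeps per day
#' at most `per_day_cap` events with the highest onset speeds (ties broken by
#' earlier onset time). Every event receives a `kept` flag and a
#' `reject_reason` ("" for survivors).
#'
#' @param events annotated events from [annotate_events()].
#' @param per_day_cap maximum events retained per recording day.
#' @return events with `kept` and `reject_reason` columns.
#' @export
prune_events <- function(events, per_day_cap = 200) {
  n <- nrow(events)
  reason <- character(n)
  reason[is.na(events$quad_r2)] <- "quad_fit_undefined"
  ok <- reason == ""
  bad_dur <- ok & (events$duration < 0.5 | events$duration > 4)
  reason[bad_dur] <- "duration"
  ok <- reason == ""
  bad_conf <- ok & events$mean_confidence <= 0.4
  reason[bad_conf] <- "confidence"
  ok <- reason == ""
  bad_quad <- ok & events$quad_r2 <= 0.6
  reason[bad_quad] <- "quad_r2"
  keep <- reason == ""
  for (d in unique(events$day)) {
    idx <- which(keep & events$day == d)
    if (length(idx) > per_day_cap) {
      ord <- idx[order(-events$onset_speed[idx], events$onset_time[idx])]
      drop <- ord[-seq_len(per_day_cap)]
      keep[drop] <- FALSE
      reason[drop] <- "day_cap"
    }
  }
  events$kept <- keep
  events$reject_reason <- reason
  events
}

#' Detect, annotate and prune events in one call
#'
#' Optionally removes events whose onset falls inside user-supplied exclusion
#' intervals (e.g., sleep or private periods) before pruning.
#'
#' @param states a [state_sequence()].
#' @param traj matching [wrist_trajectory()].
#' @param day,day_start_time passed to [detect_onsets()].
#' @param exclude optional data.frame with `start`, `end` columns (s).
#' @param per_day_cap see [prune_events()].
#' @return annotated, pruned event table.
#' @export
find_events <- function(states, traj, day = 1L, day_start_time = 0,
                        exclude = NULL, per_day_cap = 200) {
  ev <- detect_onsets(states, traj$frame_rate, day, day_start_time)
  ev$event_id <- seq_len(nrow(ev))
  if (nrow(ev) > 0 && !is.null(exclude)) {
    excl <- vapply(ev$onset_time, function(t)
      any(t >= exclude$start & t <= exclude$end), TRUE)
    ev <- ev[!excl, , drop = FALSE]
  }
  if (nrow(ev) == 0) {
    ev <- annotate_events(ev, traj)
    ev$kept <- logical(0)
    ev$reject_reason <- character(0)
    return(ev)
  }
  prune_events(annotate_events(ev, traj), per_day_cap)
}
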