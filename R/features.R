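# Per-event behavioral and environmental metadata features: timing (day,
# 8 h time-of-day bin), reach kinematics (duration, magnitude, angle, onset
# speed), speech ratio from audio, and bimanual coupling (ratio, overlap,
# class). These ten features form the design matrix of the event-by-event
# regression.

#' Fold a raw 2D reach angle onto the vertical axis
#'
#' Angles in (90, 270) degrees are reflected about the vertical so the
#' result lies in [-90, 90]: +90 = straight up, -90 = straight down, and
#' left/right reaches of equal elevation map to the same value.
#'
#' @param raw_angle_deg angle in [0, 360) (counterclockwise, 0 = rightward,
#'   90 = up).
#' @return folded angle in [-90, 90] degrees.
#' @export
transform_angle <- function(raw_angle_deg) {
  a <- raw_angle_deg %% 360
  a <- ifelse(a > 180, a - 360, a)     # signed angle in (-180, 180]
  a <- ifelse(a > 90, 180 - a, a)
  a <- ifelse(a < -90, -180 - a, a)
  a
}

# First-order low-pass (exponential) smoother with cutoff fc (Hz) at
# sampling interval dt (s).
lowpass_first_order <- function(x, fc, dt) {
  rc <- 1 / (2 * pi * fc)
  alpha <- dt / (rc + dt)
  y <- numeric(length(x))
  y[1] <- x[1]
  for (i in seq_along(x)[-1]) y[i] <- y[i - 1] + alpha * (x[i] - y[i - 1])
  y
}

#' Speech ratio around a movement event
#'
#' Short-time (1 s window, 0.5 s hop) spectral power in the speech proxy
#' band (370-900 Hz) divided by total power per frame, optionally after a
#' 40 dB spectral gate relative to a supplied rest-noise magnitude profile,
#' smoothed by a first-order low-pass (4.2 mHz cutoff) and averaged over
#' [-1, 1] s around the event onset. Scale-invariant by construction.
#'
#' @param audio an [audio_track()].
#' @param event_time onset time in seconds.
#' @param band speech band (Hz).
#' @param cutoff smoothing cutoff (Hz); 0.0042 = 4.2 mHz.
#' @param window averaging window around the event (s).
#' @param noise_profile optional per-bin magnitude profile of a rest-noise
#'   period; bins within `gate_margin` dB of (or below) the profile are
#'   attenuated by 40 dB.
#' @param gate_margin margin above the noise profile still considered noise
#'   (dB).
#' @param smooth apply the low-pass smoother (disable for closed-form
#'   checks).
#' @return speech ratio in [0, 1].
#' @export
speech_ratio <- function(audio, event_time, band = c(370, 900),
                         cutoff = 0.0042, window = c(-1, 1),
                         noise_profile = NULL, gate_margin = 6,
                         smooth = TRUE, series = NULL) {
  stopifnot(inherits(audio, "audio_track"))
  dur <- length(audio$samples) / audio$sample_rate
  if (event_time + window[1] < 0 || event_time + window[2] > dur)
    stop("event window outside audio track")
  if (is.null(series))
    series <- speech_ratio_series(audio, band, cutoff, noise_profile,
                                  gate_margin, smooth)
  sel <- series$times >= event_time + window[1] &
         series$times <= event_time + window[2]
  if (!any(sel)) sel <- which.min(abs(series$times - event_time))
  min(max(mean(series$ratio[sel]), 0), 1)
}

#' Short-time speech-band power ratio over a whole track
#'
#' The per-frame series [speech_ratio()] averages over; computing it once
#' per track and passing it via `series` avoids repeating the short-time
#' transform for every event.
#'
#' @inheritParams speech_ratio
#' @return list with `times` (frame centers, s) and `ratio`.
#' @export
speech_ratio_series <- function(audio, band = c(370, 900), cutoff = 0.0042,
                                noise_profile = NULL, gate_margin = 6,
                                smooth = TRUE) {
  stopifnot(inherits(audio, "audio_track"))
  fs <- audio$sample_rate
  wlen <- round(fs)                        # 1 s analysis window
  hop <- round(fs / 2)                     # 0.5 s hop
  starts <- seq(1, length(audio$samples) - wlen + 1, by = hop)
  freqs <- (seq_len(wlen %/% 2 + 1) - 1) * fs / wlen
  bsel <- freqs >= band[1] & freqs <= band[2]
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / (wlen + 1))
  ratio <- numeric(length(starts))
  for (i in seq_along(starts)) {
    seg <- audio$samples[starts[i]:(starts[i] + wlen - 1)] * hann
    mag <- Mod(stats::fft(seg))[seq_along(freqs)]
    if (!is.null(noise_profile)) {
      gated <- mag <= noise_profile * 10^(gate_margin / 20)
      mag[gated] <- mag[gated] * 10^(-40 / 20)
    }
    pow <- mag^2
    tot <- sum(pow)
    ratio[i] <- if (tot > 0) sum(pow[bsel]) / tot else 0
  }
  if (smooth) ratio <- lowpass_first_order(ratio, cutoff, hop / fs)
  list(times = (starts - 1 + wlen / 2) / fs, ratio = ratio)
}

# Magnitude spectrum profile of a rest-noise period, for the spectral gate.
noise_profile_from <- function(audio, start, end) {
  fs <- audio$sample_rate
  wlen <- round(fs)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / (wlen + 1))
  idx <- seq(round(start * fs) + 1, round(end * fs) - wlen, by = wlen)
  mags <- vapply(idx, function(s) {
    Mod(stats::fft(audio$samples[s:(s + wlen - 1)] * hann))[seq_len(wlen %/% 2 + 1)]
  }, numeric(wlen %/% 2 + 1))
  rowMeans(mags)
}

#' Bimanual coupling features for one contralateral event
#'
#' @param contra_traj,ipsi_traj [wrist_trajectory()] objects for both wrists.
#' @param contra_states,ipsi_states matching [state_sequence()] objects.
#' @param event one event row (contralateral onset and move dwell).
#' @return list with `ratio` (ipsilateral share of summed reach magnitudes),
#'   `overlap` (fraction of contralateral move-dwell frames with the
#'   ipsilateral wrist in move) and `class` (1 = bimanual: at least four
#'   consecutive ipsilateral move frames begin within 1 s before onset or
#'   during the contralateral move dwell).
#' @export
bimanual_features <- function(contra_traj, ipsi_traj, contra_states,
                              ipsi_states, event) {
  frames <- event$onset_frame:event$move_end_frame
  contra_mag <- max(radial_displacement(contra_traj, event$onset_frame, frames))
  ifr <- frames[frames <= length(ipsi_traj)]
  ipsi_mag <- if (length(ifr) > 1)
    max(radial_displacement(ipsi_traj, ifr[1], ifr)) else 0
  tot <- contra_mag + ipsi_mag
  if (tot == 0) {
    warning("both reach magnitudes are zero; bimanual ratio set to 0")
    ratio <- 0
  } else ratio <- ipsi_mag / tot
  ipsi_move <- ipsi_states$labels == "move"
  overlap <- mean(ipsi_move[ifr])
  lag_frames <- round(contra_traj$frame_rate)
  lo <- max(1, event$onset_frame - lag_frames)
  hi <- event$move_end_frame
  runs <- rle(ipsi_move)
  rstart <- cumsum(runs$lengths) - runs$lengths + 1
  bim <- any(runs$values & runs$lengths >= 4 & rstart >= lo & rstart <= hi)
  list(ratio = overlap_clip(ratio), overlap = overlap_clip(overlap),
       class = as.integer(bim))
}

overlap_clip <- function(x) min(max(x, 0), 1)

#' Timing features of an event
#'
#' @param event event row with `day` and `clock_time` (s of day).
#' @return list with `day` (integer) and `time_of_day` bin: half-open 8 h
#'   bins 1 = [00:00, 08:00), 2 = [08:00, 16:00), 3 = [16:00, 24:00).
#' @export
timing_features <- function(event) {
  bin <- findInterval(event$clock_time, c(0, 8, 16) * 3600)
  list(day = as.integer(event$day), time_of_day = as.integer(bin))
}

#' Build the ten-feature table for a set of kept events
#'
#' @param events pruned event table (kept rows only are used).
#' @param contra_traj,ipsi_traj,contra_states,ipsi_states wrist data for
#'   both arms.
#' @param audio optional [audio_track()] for the speech ratio (0 when
#'   absent).
#' @param noise_profile optional spectral gate profile for [speech_ratio()].
#' @return data.frame, one row per kept event, with columns event_id, day,
#'   time_of_day, duration, magnitude, angle, onset_speed, speech_ratio,
#'   bimanual_ratio, bimanual_overlap, bimanual_class.
#' @export
feature_table <- function(events, contra_traj, ipsi_traj, contra_states,
                          ipsi_states, audio = NULL, noise_profile = NULL) {
  ev <- events[events$kept, , drop = FALSE]
  if (is.null(ev$event_id)) ev$event_id <- seq_len(nrow(ev))
  sr_series <- if (!is.null(audio))
    speech_ratio_series(audio, noise_profile = noise_profile)
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    e <- ev[i, ]
    tf <- timing_features(e)
    bf <- bimanual_features(contra_traj, ipsi_traj, contra_states,
                            ipsi_states, e)
    sr <- if (is.null(audio)) 0 else
      speech_ratio(audio, e$onset_time, series = sr_series)
    data.frame(event_id = e$event_id, day = tf$day,
               time_of_day = tf$time_of_day, duration = e$duration,
               magnitude = e$reach_magnitude, angle = e$reach_angle,
               onset_speed = e$onset_speed, speech_ratio = sr,
               bimanual_ratio = bf$ratio, bimanual_overlap = bf$overlap,
               bimanual_class = bf$class)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(event_id = integer(0), day = integer(0),
                      time_of_day = integer(0), duration = numeric(0),
                      magnitude = numeric(0), angle = numeric(0),
                      onset_speed = numeric(0), speech_ratio = numeric(0),
                      bimanual_ratio = numeric(0),
                      bimanual_overlap = numeric(0),
                      bimanual_class = integer(0))
  stopifnot(!anyNA(out))
  out
}
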