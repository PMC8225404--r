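# S3 containers shared across the pipeline.

#' Wrist trajectory
#'
#' Per-frame 2D wrist keypoint path with tracking confidence. Positions are in
#' image pixels with y increasing downward (camera convention), so "up" means
#' decreasing y. Roughly 3 pixels correspond to 1 cm at the nominal camera
#' distance; this scale is carried as metadata only.
#'
#' @param x,y numeric vectors of pixel coordinates, one value per frame.
#' @param confidence per-frame tracking confidence in [0, 1].
#' @param frame_rate frames per second (> 0).
#' @param wrist_side "contralateral" or "ipsilateral" to the recorded
#'   hemisphere.
#' @return object of class `wrist_trajectory`.
#' @export
wrist_trajectory <- function(x, y, confidence = rep(1, length(x)),
                             frame_rate = 30,
                             wrist_side = c("contralateral", "ipsilateral")) {
  wrist_side <- match.arg(wrist_side)
  if (length(x) != length(y) || length(x) != length(confidence))
    stop("x, y and confidence must have the same length")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (any(confidence < 0 | confidence > 1, na.rm = TRUE))
    stop("confidence must lie in [0, 1]")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 confidence = as.numeric(confidence),
                 frame_rate = frame_rate, wrist_side = wrist_side,
                 pixels_per_cm = 3),
            class = "wrist_trajectory")
}

#' @export
length.wrist_trajectory <- function(x) length(x$x)

#' @export
print.wrist_trajectory <- function(x, ...) {
  cat(sprintf("<wrist_trajectory: %d frames @ %g fps, %s>\n",
              length(x), x$frame_rate, x$wrist_side))
  invisible(x)
}

#' Move/rest state sequence
#'
#' @param labels character or factor vector with values "rest"/"move", one per
#'   frame.
#' @param posterior optional per-frame decode confidence.
#' @param source "fitted" or "ground-truth".
#' @return object of class `state_sequence`.
#' @export
state_sequence <- function(labels, posterior = NULL,
                           source = c("fitted", "ground-truth")) {
  source <- match.arg(source)
  labels <- as.character(labels)
  if (!all(labels %in% c("rest", "move")))
    stop("labels must be 'rest' or 'move'")
  if (!is.null(posterior) && length(posterior) != length(labels))
    stop("posterior must match labels length")
  structure(list(labels = labels, posterior = posterior, source = source),
            class = "state_sequence")
}

#' @export
length.state_sequence <- function(x) length(x$labels)

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("<state_sequence: %d frames, %.1f%% move, %s>\n",
              length(x), 100 * mean(x$labels == "move"), x$source))
  invisible(x)
}

#' Multichannel neural recording
#'
#' @param voltages channels x samples matrix (microvolts).
#' @param sample_rate Hz.
#' @param channel_names character vector, one per channel.
#' @param positions channels x 3 matrix of (x, y, z) positions in mm
#'   (MNI-like; negative x = left hemisphere by convention).
#' @param group electrode group label per channel (grid/strip/depth id).
#' @param hemisphere "left" or "right" (implant hemisphere of the subject).
#' @param is_motor logical per channel; used by the synthetic generator to
#'   decide which channels carry injected movement effects.
#' @return object of class `neural_recording`.
#' @export
neural_recording <- function(voltages, sample_rate, channel_names = NULL,
                             positions = NULL, group = NULL,
                             hemisphere = "left", is_motor = NULL) {
  voltages <- as.matrix(voltages)
  nch <- nrow(voltages)
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(nch))
  if (is.null(positions)) positions <- matrix(0, nch, 3)
  positions <- as.matrix(positions)
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (nrow(positions) != nch || ncol(positions) != 3)
    stop("positions must be channels x 3")
  if (is.null(group)) group <- rep("g1", nch)
  if (is.null(is_motor)) is_motor <- rep(FALSE, nch)
  structure(list(voltages = voltages, sample_rate = sample_rate,
                 channel_names = channel_names, positions = positions,
                 group = as.character(group), hemisphere = hemisphere,
                 is_motor = is_motor,
                 bad_channels = rep(FALSE, nch),
                 zeroed_mask = rep(FALSE, ncol(voltages))),
            class = "neural_recording")
}

#' @export
print.neural_recording <- function(x, ...) {
  cat(sprintf(
    "<neural_recording: %d ch x %d samples @ %g Hz, %d bad, %.2f%% zeroed>\n",
    nrow(x$voltages), ncol(x$voltages), x$sample_rate,
    sum(x$bad_channels), 100 * mean(x$zeroed_mask)))
  invisible(x)
}

#' Audio track
#'
#' @param samples mono waveform in [-1, 1].
#' @param sample_rate Hz.
#' @return object of class `audio_track`.
#' @export
audio_track <- function(samples, sample_rate) {
  if (sample_rate <= 0) stop("sample_rate must be positive")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "audio_track")
}

#' Atlas region point sets
#'
#' @param regions named list of n x 3 matrices of region point coordinates
#'   (mm). Left hemisphere has x <= 0 under the default convention.
#' @return object of class `atlas_regions`.
#' @export
atlas_regions <- function(regions) {
  if (length(regions) == 0) stop("atlas must contain at least one region")
  if (is.null(names(regions)) || anyDuplicated(names(regions)))
    stop("regions must be uniquely named")
  regions <- lapply(regions, function(p) {
    p <- as.matrix(p)
    if (nrow(p) == 0 || ncol(p) != 3) stop("region point sets must be n x 3")
    p
  })
  structure(list(regions = regions), class = "atlas_regions")
}

#' Time-frequency log-power plane for one channel around one event
#'
#' @param power frequency x time matrix of log power (dB).
#' @param freqs frequency grid (Hz), strictly increasing.
#' @param times time grid (s, 0 = movement onset), strictly increasing.
#' @param baseline_subtracted logical flag.
#' @param baseline baseline window (s) used/intended for subtraction.
#' @return object of class `spectrogram`.
#' @export
spectrogram <- function(power, freqs, times, baseline_subtracted = FALSE,
                        baseline = c(-1.5, -1)) {
  power <- as.matrix(power)
  if (any(diff(freqs) <= 0) || any(diff(times) <= 0))
    stop("frequency and time grids must be strictly increasing")
  if (nrow(power) != length(freqs) || ncol(power) != length(times))
    stop("power must be length(freqs) x length(times)")
  structure(list(power = power, freqs = freqs, times = times,
                 baseline_subtracted = baseline_subtracted,
                 baseline = baseline),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram: %d freqs x %d times, baseline%s subtracted>\n",
              length(x$freqs), length(x$times),
              if (x$baseline_subtracted) "" else " not"))
  invisible(x)
}

# Canonical frequency bands (Hz), closed intervals on bin centers.
band_limits <- function(band) {
  switch(band,
         LFB = c(8, 32),
         HFB = c(76, 100),
         stop("unknown band: ", band))
}
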