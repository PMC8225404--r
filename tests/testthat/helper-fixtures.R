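# Shared fixture builders: everything is generated in code at test time.

# Event segment wrapper around a raw signal (single- or multi-channel).
make_segment <- function(x, fs = 500, event_id = 1) {
  v <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  structure(list(event_id = event_id, voltages = v, sample_rate = fs,
                 onset_index = (ncol(v) %/% 2) + 1, zeroed = 0),
            class = "event_segment")
}

# 10 s sinusoid segment at 500 Hz.
tone_segment <- function(freq, amp = 1, fs = 500, event_id = 1) {
  t <- seq_len(10 * fs) / fs
  make_segment(amp * sin(2 * pi * freq * t), fs, event_id)
}

# Trajectory holding still except for prescribed move excursions.
# moves: data.frame(onset, len, mag, angle_deg) in frames/pixels.
make_traj <- function(n_frames, moves = NULL, frame_rate = 30,
                      confidence = rep(1, n_frames), noise = 0, seed = 1) {
  set.seed(seed)
  x <- rep(100, n_frames); y <- rep(100, n_frames)
  if (!is.null(moves)) {
    for (i in seq_len(nrow(moves))) {
      m <- moves[i, ]
      fr <- m$onset:(m$onset + m$len - 1)
      u <- (seq_along(fr) - 1) / max(length(fr) - 1, 1)
      r <- m$mag * 4 * u * (1 - u)
      x[fr] <- 100 + r * cos(m$angle_deg * pi / 180)
      y[fr] <- 100 - r * sin(m$angle_deg * pi / 180)
    }
  }
  if (noise > 0) {
    x <- x + rnorm(n_frames, 0, noise)
    y <- y + rnorm(n_frames, 0, noise)
  }
  wrist_trajectory(x, y, confidence, frame_rate)
}

# Labels from run-length pairs, e.g. lab_runs(c(rest = 15, move = 15)).
lab_runs <- function(runs) rep(names(runs), runs)

# Random dwell parameter pair for HSMM engine property tests.
random_dwell <- function() {
  list(list(size = runif(1, 0.3, 5), mean = 1 + runif(1, 0.3, 6)),
       list(size = runif(1, 0.3, 5), mean = 1 + runif(1, 0.3, 6)))
}

# Tiny synthetic config used by several suites.
tiny_config <- function(...) {
  synthetic_config(n_subjects = 1, days = 1:2, events_per_day = 12,
                   n_channels = 4, neural_rate = 500, noise_sd = 0.5,
                   seed = 7, ...)
}
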