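# Synthetic multi-subject, multi-day studies with known ground truth:
# semi-Markov move/rest wrist trajectories, pink-noise neural recordings
# with event-locked band-power changes following the linear feature model,
# speech-band audio, electrode layouts and a point-cloud atlas.
#
# The generator's defaults state the emulated world once: 30 fps video,
# 1000 Hz neural sampling, rest dwells averaging 60 frames and move dwells
# 45 frames (negative binomial, shifted so every move lasts >= 0.5 s and
# every rest >= 1.5 s, keeping the pre-onset baseline clean), reach
# magnitudes right-skewed below ~200 px, reach angles bimodal at +-90
# degrees, and 90% of movements parabolic.

#' Synthetic study configuration
#'
#' @param n_subjects number of subjects.
#' @param days vector of recording-day indices (nonempty).
#' @param frame_rate video rate, Hz.
#' @param neural_rate neural sampling rate, Hz.
#' @param n_channels electrodes per subject.
#' @param events_per_day true movement-initiation events per subject-day.
#' @param true_betas named list mapping feature names to c(LFB, HFB)
#'   coefficients in dB per standardized unit (day coefficients are offsets
#'   for the named day level, e.g. `day.2`).
#' @param beta0 intercept c(LFB, HFB) in dB.
#' @param noise_sd per-event dB noise on the injected band changes.
#' @param duration_params list with `rest` and `move`, each
#'   list(mean, size) for the negative binomial dwell laws (frames).
#' @param traj_noise_sd pixel jitter on wrist positions (all frames).
#' @param move_jitter_sd extra pixel jitter during move frames: wrists in
#'   motion are tracked less precisely and real reaches are never purely
#'   radial, so within-move velocity stays bounded away from zero.
#' @param parabolic_frac fraction of movements with parabolic radial
#'   profiles.
#' @param bimanual_frac fraction of movements mirrored by the other wrist.
#' @param day_start_time clock time (s of day) of the first frame.
#' @param seed master seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 2, days = 1:3, frame_rate = 30,
                             neural_rate = 1000, n_channels = 8,
                             events_per_day = 100,
                             true_betas = list(),
                             beta0 = c(LFB = -1.5, HFB = 1),
                             noise_sd = 0.5,
                             duration_params = list(
                               rest = list(mean = 60, size = 5),
                               move = list(mean = 45, size = 5)),
                             traj_noise_sd = 0.3,
                             move_jitter_sd = 1,
                             parabolic_frac = 0.9,
                             bimanual_frac = 0.4,
                             day_start_time = 7.9 * 3600,
                             seed = 1) {
  if (frame_rate <= 0 || neural_rate <= 0)
    stop("invalid config: rates must be positive")
  if (length(days) == 0) stop("invalid config: days must be nonempty")
  if (noise_sd < 0) stop("invalid config: noise_sd must be >= 0")
  for (s in c("rest", "move")) {
    dp <- duration_params[[s]]
    if (is.null(dp) || dp$mean <= 0 || dp$size <= 0)
      stop("invalid config: nonpositive dwell parameters for ", s)
  }
  structure(list(n_subjects = n_subjects, days = days,
                 frame_rate = frame_rate, neural_rate = neural_rate,
                 n_channels = n_channels, events_per_day = events_per_day,
                 true_betas = true_betas, beta0 = beta0, noise_sd = noise_sd,
                 duration_params = duration_params,
                 traj_noise_sd = traj_noise_sd,
                 move_jitter_sd = move_jitter_sd,
                 parabolic_frac = parabolic_frac,
                 bimanual_frac = bimanual_frac,
                 day_start_time = day_start_time, seed = seed),
            class = "synthetic_config")
}

# Shifted negative binomial dwell sample: mind + NB(size, mu = mean - mind).
sample_dwell <- function(n, mean, size, mind) {
  mu <- max(mean - mind, 0.5)
  mind + stats::rnbinom(n, size = size, mu = mu)
}

# Reach angle marginal: bimodal at +-90 deg (up/down) with 10% uniform.
sample_angle_raw <- function(n) {
  u <- stats::runif(n)
  ang <- ifelse(u < 0.45, 90 + stats::rnorm(n, 0, 15),
         ifelse(u < 0.90, 270 + stats::rnorm(n, 0, 15),
                stats::runif(n, 0, 360)))
  ang %% 360
}

#' Simulate one subject-day wrist trajectory pair with ground truth
#'
#' Alternating rest/move dwells from the configured negative binomial laws
#' (rest shifted to >= 1.5 s, move to >= 0.5 s, so every move onset is a
#' detectable event); move segments trace parabolic radial excursions in a
#' sampled direction (a configurable fraction instead follow jittery random
#' walks that fail the quadratic-fit screen); rest segments hold position.
#' Pixel jitter is added everywhere; confidence is high with occasional
#' dips below 0.4. The ipsilateral wrist mirrors a configurable fraction of
#' movements.
#'
#' @param config a [synthetic_config()].
#' @param subject,day indices (used to vary the derived seed).
#' @param seed seed for this subject-day.
#' @return list with `contra` and `ipsi` [wrist_trajectory()]s, ground-truth
#'   [state_sequence()]s `contra_states` and `ipsi_states`, and
#'   `truth` (data.frame of true onsets/dwells/kinematics, one row per
#'   event).
#' @export
generate_trajectory <- function(config, subject = 1, day = 1,
                                seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fr <- config$frame_rate
  min_move <- ceiling(0.5 * fr)
  min_rest <- ceiling(1.5 * fr)
  lead <- ceiling(6 * fr)                  # margin for 10 s neural windows
  ne <- config$events_per_day
  dp <- config$duration_params
  rest_d <- sample_dwell(ne + 1, dp$rest$mean, dp$rest$size, min_rest)
  move_d <- sample_dwell(ne, dp$move$mean, dp$move$size, min_move)
  rest_d[1] <- rest_d[1] + lead
  rest_d[ne + 1] <- rest_d[ne + 1] + lead
  n_frames <- sum(rest_d) + sum(move_d)
  labels <- character(n_frames)
  x <- numeric(n_frames); y <- numeric(n_frames)
  xi <- numeric(n_frames); yi <- numeric(n_frames)
  ipsi_move <- rep(FALSE, n_frames)
  cx <- 320; cy <- 240                    # nominal frame center, pixels
  cxi <- 280; cyi <- 240
  mags <- pmin(pmax(stats::rlnorm(ne, log(60), 0.5), 15), 250)
  angs <- sample_angle_raw(ne)
  parab <- stats::runif(ne) < config$parabolic_frac
  biman <- stats::runif(ne) < config$bimanual_frac
  # ipsilateral co-movements vary in onset lag, length and size so the
  # bimanual ratio/overlap/class features are correlated but not collinear
  ipsi_lag <- round(stats::runif(ne, -0.8, 0.5) * fr)
  ipsi_len_frac <- stats::runif(ne, 0.4, 1.2)
  ipsi_scale <- stats::runif(ne, 0.3, 1.5)
  flicker <- !biman & stats::runif(ne) < 0.15
  truth <- data.frame(event = seq_len(ne), onset_frame = NA_integer_,
                      move_frames = move_d, magnitude = mags,
                      angle_raw = angs, parabolic = parab,
                      bimanual = biman)
  pos <- 0
  ipsi_plan <- list()
  for (ev in seq_len(ne + 1)) {
    rd <- rest_d[ev]
    labels[pos + seq_len(rd)] <- "rest"
    x[pos + seq_len(rd)] <- cx
    y[pos + seq_len(rd)] <- cy
    xi[pos + seq_len(rd)] <- cxi
    yi[pos + seq_len(rd)] <- cyi
    pos <- pos + rd
    if (ev > ne) break
    md <- move_d[ev]
    labels[pos + seq_len(md)] <- "move"
    truth$onset_frame[ev] <- pos + 1
    if (parab[ev]) {
      u <- (seq_len(md) - 1) / max(md - 1, 1)
      r <- mags[ev] * 4 * u * (1 - u)
      dx <- r * cos(angs[ev] * pi / 180)
      dy <- -r * sin(angs[ev] * pi / 180)   # pixel y grows downward
    } else {
      dx <- cumsum(stats::rnorm(md, 0, 4))
      dy <- cumsum(stats::rnorm(md, 0, 4))
    }
    x[pos + seq_len(md)] <- cx + dx
    y[pos + seq_len(md)] <- cy + dy
    xi[pos + seq_len(md)] <- cxi
    yi[pos + seq_len(md)] <- cyi
    if (biman[ev]) {
      mi <- max(4, round(md * ipsi_len_frac[ev]))
      a <- max(1, pos + 1 + ipsi_lag[ev])
      ipsi_plan[[length(ipsi_plan) + 1]] <-
        list(frames = a:min(a + mi - 1, n_frames), ev = ev)
    } else if (flicker[ev]) {
      ipsi_plan[[length(ipsi_plan) + 1]] <-
        list(frames = pos + 1:3, ev = ev, flick = TRUE)
    }
    pos <- pos + md
  }
  for (pl in ipsi_plan) {                  # second pass: ipsi co-movements
    fi <- pl$frames
    if (isTRUE(pl$flick)) {
      xi[fi] <- cxi + 5                    # 3-frame flicker, stays unimanual
      ipsi_move[fi] <- TRUE
      next
    }
    u <- (seq_along(fi) - 1) / max(length(fi) - 1, 1)
    ri <- ipsi_scale[pl$ev] * mags[pl$ev] * 4 * u * (1 - u)
    xi[fi] <- cxi - ri * cos(angs[pl$ev] * pi / 180)
    yi[fi] <- cyi - ri * sin(angs[pl$ev] * pi / 180)
    ipsi_move[fi] <- TRUE
  }
  ns <- config$traj_noise_sd
  if (ns > 0) {
    x <- x + stats::rnorm(n_frames, 0, ns)
    y <- y + stats::rnorm(n_frames, 0, ns)
    xi <- xi + stats::rnorm(n_frames, 0, ns)
    yi <- yi + stats::rnorm(n_frames, 0, ns)
  }
  mj <- config$move_jitter_sd * (config$traj_noise_sd > 0)
  if (mj > 0) {
    mv <- labels == "move"
    x[mv] <- x[mv] + stats::rnorm(sum(mv), 0, mj)
    y[mv] <- y[mv] + stats::rnorm(sum(mv), 0, mj)
    yi[ipsi_move] <- yi[ipsi_move] + stats::rnorm(sum(ipsi_move), 0, mj)
    xi[ipsi_move] <- xi[ipsi_move] + stats::rnorm(sum(ipsi_move), 0, mj)
  }
  conf <- stats::rbeta(n_frames, 20, 2)
  dip <- stats::runif(n_frames) < 0.02
  conf[dip] <- stats::rbeta(sum(dip), 2, 6)
  contra <- wrist_trajectory(x, y, conf, fr, "contralateral")
  ipsi <- wrist_trajectory(xi, yi, stats::rbeta(n_frames, 20, 2), fr,
                           "ipsilateral")
  ipsi_labels <- ifelse(ipsi_move, "move", "rest")
  list(contra = contra, ipsi = ipsi,
       contra_states = state_sequence(labels, source = "ground-truth"),
       ipsi_states = state_sequence(ipsi_labels, source = "ground-truth"),
       truth = truth)
}

#' Synthetic electrode layout
#'
#' A grid of electrodes over left sensorimotor cortex (MNI-like mm
#' coordinates); channels within 25 mm of the precentral seed are marked
#' "motor" and carry the injected movement effects.
#'
#' @param n_channels number of electrodes.
#' @param hemisphere implant hemisphere.
#' @return list with `positions`, `names`, `group`, `is_motor`,
#'   `hemisphere`.
#' @export
synthetic_layout <- function(n_channels = 8, hemisphere = "left") {
  rows <- ceiling(sqrt(n_channels))
  gx <- seq(0, rows - 1) * 10
  grid <- expand.grid(dy = gx, dz = gx)[seq_len(n_channels), ]
  seed_pos <- c(-42, -12, 52)              # near precentral gyrus
  pos <- cbind(seed_pos[1], seed_pos[2] + grid$dy - 15,
               seed_pos[3] + grid$dz - 15)
  if (hemisphere == "right") pos[, 1] <- -pos[, 1]
  d <- sqrt(rowSums(sweep(pos, 2, c(sign(pos[1, 1]) * 42, -12, 52))^2))
  list(positions = pos, names = sprintf("G%02d", seq_len(n_channels)),
       group = rep("grid1", n_channels), is_motor = d < 25,
       hemisphere = hemisphere)
}

#' Synthetic atlas of eight cortical regions
#'
#' Point clouds (mm) around canonical left-hemisphere frontoparietal and
#' temporal locations, standing in for a parcellation the package does not
#' ship.
#'
#' @param points_per_region cloud size.
#' @param seed RNG seed.
#' @return an [atlas_regions()] object.
#' @export
synthetic_atlas <- function(points_per_region = 40, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  centers <- list(
    middle_frontal    = c(-38,  30,  34),
    precentral        = c(-42, -12,  52),
    postcentral       = c(-44, -24,  48),
    inferior_parietal = c(-44, -46,  46),
    supramarginal     = c(-56, -40,  32),
    superior_temporal = c(-56, -20,   4),
    middle_temporal   = c(-58, -36,  -4),
    inferior_temporal = c(-52, -44, -18))
  atlas_regions(lapply(centers, function(ctr) {
    sweep(matrix(stats::rnorm(points_per_region * 3, 0, 6),
                 points_per_region, 3), 2, ctr, `+`)
  }))
}

# Leakage calibration of the injection gain: the Morlet measurement of a
# 0.5 s boxcar band-power step recovers this fraction of the injected dB
# change (temporal smearing at the analysis wavelets, whose n_cycles = f/2
# gives the same sigma_t = 1/(4*pi) s at every band). Calibrated once on
# clean injections (150 events per sign and band) and pinned; see the
# methods vignette.
.inject_kappa <- c(LFB = 0.785, HFB = 0.785)

#' Generate a neural recording with event-locked band-power changes
#'
#' Pink-noise background on every channel; for each event, the 0.5 s after
#' onset carries an 8-32 Hz and a 76-100 Hz amplitude change on motor
#' channels, sized so that the Morlet band-averaged log-power change equals
#' beta0 + sum(beta_i x_i) + noise for that event. Non-motor channels
#' receive no injected effect.
#'
#' @param events data.frame with `onset_time` (s).
#' @param deltas data.frame/matrix with columns `LFB`, `HFB`: target dB
#'   change per event (noise already included by the caller or via
#'   `noise_sd`).
#' @param layout a [synthetic_layout()].
#' @param duration recording length (s).
#' @param rate sampling rate (Hz).
#' @param noise_sd additional per-event dB noise, applied independently per
#'   band.
#' @param seed RNG seed.
#' @param background_scale pink-noise amplitude (microvolts RMS).
#' @return a [neural_recording()].
#' @export
generate_neural <- function(events, deltas, layout, duration, rate = 1000,
                            noise_sd = 0, seed = 1, background_scale = 60) {
  if (is.unsorted(events$onset_time)) stop("events must be sorted by time")
  nch <- length(layout$names)
  if (nch < 1) stop("layout must have at least one channel")
  n <- round(duration * rate)
  for (i in seq_len(nrow(events))) {
    if (events$onset_time[i] < 0 ||
        round((events$onset_time[i] + 0.5) * rate) > n)
      stop("event ", i, " window exceeds recording bounds")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  deltas <- as.matrix(deltas)
  if (noise_sd > 0)
    deltas <- deltas + matrix(stats::rnorm(length(deltas), 0, noise_sd),
                              nrow(deltas))
  bands <- list(LFB = c(8, 32), HFB = c(76, 100))
  ntaps <- 2 * floor(0.4 * rate / 2) + 1
  hb <- lapply(bands, function(b) fir_bandpass(b[1] / rate, b[2] / rate, ntaps))
  V <- matrix(0, nch, n)
  epoch_n <- round(0.5 * rate)
  for (ch in seq_len(nch)) {
    xch <- pink_noise(n, rate, scale = background_scale)
    if (isTRUE(layout$is_motor[ch]) && nrow(events) > 0) {
      comp <- lapply(hb, function(h) filter_zerophase(xch, h))
      for (i in seq_len(nrow(events))) {
        s0 <- round(events$onset_time[i] * rate) + 1
        idx <- s0:(s0 + epoch_n - 1)
        for (b in names(bands)) {
          g <- 10^((deltas[i, b] / .inject_kappa[[b]]) / 20)
          xch[idx] <- xch[idx] + (g - 1) * comp[[b]][idx]
        }
      }
    }
    V[ch, ] <- xch
  }
  neural_recording(V, rate, layout$names, layout$positions, layout$group,
                   layout$hemisphere, layout$is_motor)
}

#' Generate an audio track with speech-band energy in given intervals
#'
#' Broadband noise floor everywhere; inside each interval, band-limited
#' (370-900 Hz) noise or a pure tone is added well above the floor.
#'
#' @param speech_intervals data.frame with `start`, `end` (s),
#'   non-overlapping and inside the track.
#' @param duration track length (s).
#' @param sample_rate Hz (>= 1800 to carry the speech band).
#' @param kind "noise" or "tone" (500 Hz).
#' @param snr amplitude ratio of speech to floor.
#' @param seed RNG seed.
#' @return an [audio_track()].
#' @export
generate_audio <- function(speech_intervals, duration, sample_rate = 2000,
                           kind = c("noise", "tone"), snr = 20, seed = 1) {
  kind <- match.arg(kind)
  si <- speech_intervals
  if (nrow(si) > 0) {
    if (any(si$end <= si$start)) stop("malformed interval (end <= start)")
    if (any(si$start < 0 | si$end > duration))
      stop("interval outside track duration")
    o <- order(si$start)
    if (any(si$start[o][-1] < si$end[o][-nrow(si)]))
      stop("overlapping speech intervals")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- round(duration * sample_rate)
  x <- stats::rnorm(n, 0, 0.005)
  if (nrow(si) > 0) {
    ntaps <- 2 * floor(0.05 * sample_rate) + 1
    h <- fir_bandpass(370 / sample_rate, 900 / sample_rate, ntaps)
    for (i in seq_len(nrow(si))) {
      idx <- (round(si$start[i] * sample_rate) + 1):
             round(si$end[i] * sample_rate)
      sig <- if (kind == "tone") {
        sin(2 * pi * 500 * (idx - 1) / sample_rate)
      } else {
        fz <- filter_zerophase(stats::rnorm(length(idx)), h)
        fz / stats::sd(fz)
      }
      x[idx] <- x[idx] + 0.005 * snr * sig
    }
  }
  audio_track(pmin(pmax(x, -1), 1), sample_rate)
}

#' Generate a complete synthetic study
#'
#' Composes trajectories, ground-truth features, neural recordings and
#' audio per subject-day, with per-event injected band changes following
#' the configured linear model on standardized features (day offsets taken
#' from `true_betas` entries named like `day.2`).
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_study`: per subject a list of days,
#'   each with `traj` (generate_trajectory output), `recording`, `audio`,
#'   plus `layout`, `atlas`, and `ground_truth` (features, deltas, betas).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  atlas <- synthetic_atlas(seed = config$seed)
  subjects <- list()
  for (s in seq_len(config$n_subjects)) {
    layout <- synthetic_layout(config$n_channels,
                               hemisphere = if (s %% 2 == 0) "right" else "left")
    days <- list()
    feats_all <- list()
    for (di in seq_along(config$days)) {
      d <- config$days[di]
      seed_sd <- (config$seed * 1009 + s * 101 + d) %% .Machine$integer.max
      tr <- generate_trajectory(config, s, d, seed = seed_sd)
      ev <- find_events(tr$contra_states, tr$contra, day = d,
                        day_start_time = config$day_start_time)
      dur <- length(tr$contra) / config$frame_rate
      n_iv <- max(1, floor(dur / 100))
      iv_start <- seq(10, dur - 15, length.out = n_iv) +
        stats::runif(n_iv, -2, 2)
      audio <- generate_audio(
        data.frame(start = iv_start, end = iv_start + 8),
        duration = dur,
        seed = (config$seed * 3001 + s * 307 + di) %% .Machine$integer.max)
      ft <- feature_table(ev, tr$contra, tr$ipsi, tr$contra_states,
                          tr$ipsi_states, audio = audio)
      ft$day_index <- di
      days[[di]] <- list(traj = tr, events = ev, audio = audio)
      feats_all[[di]] <- ft
    }
    ft_all <- do.call(rbind, feats_all)
    x <- scale(cbind(duration = log(ft_all$duration),
                     magnitude = log(pmax(ft_all$magnitude, 1e-12)),
                     angle = ft_all$angle, onset_speed = ft_all$onset_speed,
                     speech_ratio = ft_all$speech_ratio,
                     bimanual_ratio = ft_all$bimanual_ratio,
                     bimanual_overlap = ft_all$bimanual_overlap,
                     bimanual_class = ft_all$bimanual_class))
    x[is.nan(x)] <- 0                      # zero-variance columns
    deltas <- matrix(rep(config$beta0, each = nrow(ft_all)), ncol = 2,
                     dimnames = list(NULL, c("LFB", "HFB")))
    for (bn in names(config$true_betas)) {
      bv <- config$true_betas[[bn]]
      if (grepl("^day\\.", bn)) {
        lev <- as.integer(sub("^day\\.", "", bn))
        ind <- as.numeric(ft_all$day == lev)
        deltas <- deltas + outer(ind, bv)
      } else {
        deltas <- deltas + outer(x[, bn], bv)
      }
    }
    for (di in seq_along(config$days)) {
      sel <- ft_all$day_index == di
      tr <- days[[di]]$traj
      ev <- days[[di]]$events
      kept <- ev[ev$kept, , drop = FALSE]
      dur <- length(tr$contra) / config$frame_rate
      rec <- generate_neural(kept, deltas[sel, , drop = FALSE], layout,
                             duration = dur, rate = config$neural_rate,
                             noise_sd = config$noise_sd,
                             seed = (config$seed * 2003 + s * 211 + di) %%
                               .Machine$integer.max)
      days[[di]]$recording <- rec
    }
    subjects[[s]] <- list(days = days, layout = layout,
                          ground_truth = list(features = ft_all,
                                              features_std = x,
                                              deltas = deltas,
                                              true_betas = config$true_betas,
                                              beta0 = config$beta0))
  }
  structure(list(config = config, atlas = atlas, subjects = subjects),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  nev <- sum(vapply(x$subjects, function(s)
    nrow(s$ground_truth$features), 1))
  cat(sprintf("<synthetic_study: %d subjects x %d days, %d kept events>\n",
              length(x$subjects), length(x$config$days), nev))
  invisible(x)
}
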