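# Behavioral/environmental metadata features.

test_that("angle folding maps the circle onto [-90, 90] with vertical symmetry", {
  expect_equal(transform_angle(90), 90)
  expect_equal(transform_angle(270), -90)
  expect_equal(transform_angle(135), 45)
  expect_equal(transform_angle(0), 0)
  expect_equal(transform_angle(180), 0)
  grid <- seq(0, 359.5, by = 0.5)
  out <- transform_angle(grid)
  expect_true(all(out >= -90 & out <= 90))
  # idempotent on its range (interpreting outputs mod 360)
  expect_equal(transform_angle(out %% 360), out)
  # f(a) = f(180 - a): left/right mirror pairs coincide
  expect_equal(transform_angle((180 - grid) %% 360), out)
})

test_that("speech ratio isolates band energy, is scale-invariant, and errors off-track", {
  # pure tone in-band filling the analysis window, no smoothing
  iv <- data.frame(start = 2, end = 8)
  aud <- generate_audio(iv, duration = 10, kind = "tone", seed = 1)
  r_tone <- speech_ratio(aud, 5, smooth = FALSE)
  expect_gt(r_tone, 0.9)
  # silence + broadband noise floor: ratio near the band's share of the
  # total bandwidth (530 Hz of the 1000 Hz Nyquist range)
  aud0 <- generate_audio(iv[0, ], duration = 10, seed = 2)
  r_noise <- speech_ratio(aud0, 5, smooth = FALSE)
  expect_equal(r_noise, 530 / 1000, tolerance = 0.05)
  # doubling the gain changes nothing
  aud2 <- audio_track(aud$samples * 2, aud$sample_rate)
  expect_equal(speech_ratio(aud2, 5, smooth = FALSE), r_tone,
               tolerance = 1e-12)
  expect_error(speech_ratio(aud, 9.9), "outside")
  # an event inside a speech interval scores higher than one outside
  aud_iv <- generate_audio(data.frame(start = 3, end = 6), duration = 20,
                           seed = 3)
  r_in <- speech_ratio(aud_iv, 4.5, smooth = FALSE)
  r_out <- speech_ratio(aud_iv, 15, smooth = FALSE)
  expect_gt(r_in, r_out)
})

test_that("the spectral gate suppresses components at the noise-profile level", {
  ns <- getFromNamespace("noise_profile_from", "naturalreach")
  aud <- generate_audio(data.frame(start = 6, end = 9), duration = 12,
                        seed = 4)
  prof <- ns(aud, 0, 5)
  gated <- speech_ratio(aud, 7.5, noise_profile = prof, smooth = FALSE)
  plain <- speech_ratio(aud, 7.5, smooth = FALSE)
  expect_gt(gated, plain)   # floor is suppressed, band share rises
})

test_that("bimanual ratio/overlap/class follow their definitions", {
  n <- 120
  st_runs <- c(rest = 30, move = 45, rest = 45)
  contra <- make_traj(n, moves = data.frame(onset = 31, len = 45, mag = 60,
                                            angle_deg = 90))
  contra_states <- state_sequence(lab_runs(st_runs))
  ev <- data.frame(onset_frame = 31, move_end_frame = 75, duration = 1.5)
  # stationary ipsilateral wrist
  ipsi0 <- make_traj(n)
  ipsi0_states <- state_sequence(rep("rest", n))
  b0 <- suppressWarnings(
    bimanual_features(contra, ipsi0, contra_states, ipsi0_states, ev))
  expect_equal(b0$ratio, 0, tolerance = 1e-6)
  expect_equal(b0$overlap, 0)
  expect_equal(b0$class, 0L)
  # identical mirrored movement
  ipsi1 <- wrist_trajectory(200 - (contra$x - 100), contra$y,
                            wrist_side = "ipsilateral")
  b1 <- bimanual_features(contra, ipsi1, contra_states, contra_states, ev)
  expect_equal(b1$ratio, 0.5, tolerance = 1e-9)
  expect_equal(b1$overlap, 1)
  expect_equal(b1$class, 1L)
  # a 3-frame ipsilateral flicker is not bimanual
  flick <- rep("rest", n); flick[40:42] <- "move"
  b2 <- bimanual_features(contra, ipsi0, contra_states,
                          state_sequence(flick), ev)
  expect_equal(b2$class, 0L)
  # 4 consecutive frames starting within 1 s before onset count
  pre <- rep("rest", n); pre[3:6] <- "move"    # 28 frames before onset < 30
  b3 <- bimanual_features(contra, ipsi0, contra_states,
                          state_sequence(pre), ev)
  expect_equal(b3$class, 1L)
  # ... but not if it starts earlier than 1 s before onset
  pre2 <- rep("rest", n); pre2[1] <- "move"
  pre2[1:4] <- "move"
  ev_late <- data.frame(onset_frame = 61, move_end_frame = 105)
  b4 <- bimanual_features(contra, ipsi0,
                          state_sequence(lab_runs(c(rest = 60, move = 45,
                                                    rest = 15))),
                          state_sequence(pre2), ev_late)
  expect_equal(b4$class, 0L)
})

test_that("timing features bin the clock into half-open 8 h segments", {
  tf <- function(ct, d = 2) timing_features(data.frame(day = d,
                                                       clock_time = ct))
  expect_equal(tf(7 * 3600 + 59 * 60 + 59.9)$time_of_day, 1L)
  expect_equal(tf(8 * 3600)$time_of_day, 2L)
  expect_equal(tf(23.5 * 3600)$time_of_day, 3L)
  expect_equal(tf(0)$time_of_day, 1L)
  expect_equal(tf(100, d = 5)$day, 5L)
})

test_that("all ten features are computed with no missing values on synthetic data", {
  cfg <- tiny_config()
  tr <- generate_trajectory(cfg, 1, 1, seed = 3)
  ev <- find_events(tr$contra_states, tr$contra, day = 1,
                    day_start_time = cfg$day_start_time)
  aud <- generate_audio(data.frame(start = 5, end = 10),
                        duration = length(tr$contra) / 30, seed = 5)
  ft <- feature_table(ev, tr$contra, tr$ipsi, tr$contra_states,
                      tr$ipsi_states, audio = aud)
  expect_equal(nrow(ft), sum(ev$kept))
  expect_false(anyNA(ft))
  expect_setequal(names(ft), c("event_id", "day", "time_of_day", "duration",
                               "magnitude", "angle", "onset_speed",
                               "speech_ratio", "bimanual_ratio",
                               "bimanual_overlap", "bimanual_class"))
  expect_true(all(ft$angle >= -90 & ft$angle <= 90))
  expect_true(all(ft$speech_ratio >= 0 & ft$speech_ratio <= 1))
  expect_true(all(ft$bimanual_ratio >= 0 & ft$bimanual_ratio <= 1))
})
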