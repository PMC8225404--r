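# The synthetic-study generator: validation, determinism, distributional
# contracts, and the forward model for the injected neural effects.

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(days = integer(0)), "days")
  expect_error(synthetic_config(frame_rate = 0), "rates")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
  expect_error(synthetic_config(duration_params = list(
    rest = list(mean = -5, size = 2), move = list(mean = 45, size = 5))),
    "nonpositive dwell")
})

test_that("trajectories are deterministic and carry exact ground truth in the noiseless limit", {
  cfg <- synthetic_config(events_per_day = 5, traj_noise_sd = 0, seed = 3)
  a <- generate_trajectory(cfg, 1, 1, seed = 11)
  b <- generate_trajectory(cfg, 1, 1, seed = 11)
  expect_identical(a$contra$x, b$contra$x)
  expect_identical(a$truth, b$truth)
  # one event configured -> exactly one ground-truth move dwell and onset
  cfg1 <- synthetic_config(events_per_day = 1, traj_noise_sd = 0, seed = 4)
  tr <- generate_trajectory(cfg1, 1, 1, seed = 12)
  runs <- rle(tr$contra_states$labels)
  expect_equal(sum(runs$values == "move"), 1)
  ev <- detect_onsets(tr$contra_states, 30)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_frame, tr$truth$onset_frame)
  # ground-truth labels match the trajectory length
  expect_length(tr$contra_states$labels, length(tr$contra))
})

test_that("empirical dwell means match the configured distributions", {
  cfg <- synthetic_config(events_per_day = 120, seed = 5)
  tr <- generate_trajectory(cfg, 1, 1, seed = 13)
  runs <- rle(tr$contra_states$labels)
  # drop first/last rest runs (padded with the 6 s lead-in margin)
  rest_d <- runs$lengths[runs$values == "rest"]
  rest_d <- rest_d[-c(1, length(rest_d))]
  move_d <- runs$lengths[runs$values == "move"]
  for (pair in list(list(d = rest_d, mean = 60), list(d = move_d, mean = 45))) {
    se <- sd(pair$d) / sqrt(length(pair$d))
    expect_lt(abs(mean(pair$d) - pair$mean), 3 * se + 1e-9)
  }
  # confidence occasionally dips below the pruning threshold
  expect_gt(mean(tr$contra$confidence < 0.4), 0.001)
  expect_true(all(tr$contra$confidence >= 0 & tr$contra$confidence <= 1))
})

test_that("neural generator injects the linear model's band changes on motor channels only", {
  ne <- 60
  onsets <- seq(8, 8 + 7 * (ne - 1), by = 7)
  events <- data.frame(onset_time = onsets)
  layout <- synthetic_layout(2)
  layout$is_motor <- c(TRUE, FALSE)
  # null effect: both deltas zero -> no band change beyond estimation noise
  rec0 <- generate_neural(events, data.frame(LFB = rep(0, ne),
                                             HFB = rep(0, ne)),
                          layout, duration = max(onsets) + 8, rate = 500,
                          seed = 2)
  bp0 <- band_power_table(extract_segments(rec0, events), channels = 1)
  expect_lt(abs(mean(bp0$LFB)), 0.45)
  expect_lt(abs(mean(bp0$HFB)), 0.45)
  # planted deltas recovered on the motor channel, absent on the other
  deltas <- data.frame(LFB = rep(-3, ne), HFB = rep(2, ne))
  rec <- generate_neural(events, deltas, layout,
                         duration = max(onsets) + 8, rate = 500, seed = 2)
  bp <- band_power_table(extract_segments(rec, events), channels = 1:2)
  m <- aggregate(cbind(LFB, HFB) ~ channel, data = bp, FUN = mean)
  expect_equal(m$LFB[1], -3, tolerance = 0.6)
  expect_equal(m$HFB[1], 2, tolerance = 0.5)
  expect_lt(abs(m$LFB[2]), 0.5)
  expect_lt(abs(m$HFB[2]), 0.5)
  # a negative angle beta makes +90 degree events weaker than -90 ones
  x_angle <- rep(c(1, -1), length.out = ne)          # standardized angle
  deltas2 <- data.frame(LFB = -1.5 * x_angle, HFB = 0 * x_angle)
  rec2 <- generate_neural(events, deltas2, layout,
                          duration = max(onsets) + 8, rate = 500, seed = 3)
  bp2 <- band_power_table(extract_segments(rec2, events), channels = 1)
  up <- bp2$LFB[x_angle > 0]
  dn <- bp2$LFB[x_angle < 0]
  expect_lt(t.test(up, dn)$p.value, 1e-4)
  expect_lt(mean(up), mean(dn))
  # events outside the recording are named in the error
  expect_error(generate_neural(data.frame(onset_time = 1e5),
                               data.frame(LFB = 0, HFB = 0), layout,
                               duration = 100, rate = 500),
               "event 1")
})

test_that("audio generator puts 370-900 Hz energy only inside speech intervals", {
  aud <- generate_audio(data.frame(start = 3, end = 6), duration = 10,
                        seed = 6)
  sr <- speech_ratio_series(aud, smooth = FALSE)
  inside <- sr$ratio[sr$times > 3.5 & sr$times < 5.5]
  outside <- sr$ratio[sr$times < 2 | sr$times > 7.5]
  expect_gt(min(inside), max(outside))
  expect_error(generate_audio(data.frame(start = 5, end = 4), 10),
               "malformed")
  expect_error(generate_audio(data.frame(start = c(1, 2), end = c(3, 4)), 10),
               "overlapping")
  expect_error(generate_audio(data.frame(start = 8, end = 12), 10),
               "outside")
})

test_that("study composition is reproducible, complete, and consistent with its config", {
  cfg <- tiny_config()
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$subjects[[1]]$days[[1]]$recording$voltages,
                   s2$subjects[[1]]$days[[1]]$recording$voltages)
  expect_identical(s1$subjects[[1]]$ground_truth$features,
                   s2$subjects[[1]]$ground_truth$features)
  expect_length(s1$subjects, cfg$n_subjects)
  for (sub in s1$subjects) {
    expect_length(sub$days, length(cfg$days))
    for (day in sub$days) {
      # configured number of true events, all inside the recording
      ev <- detect_onsets(day$traj$contra_states, cfg$frame_rate)
      expect_equal(nrow(ev), cfg$events_per_day)
      rec_dur <- ncol(day$recording$voltages) / day$recording$sample_rate
      expect_true(all(ev$onset_time + 0.5 < rec_dur))
      expect_length(day$traj$contra_states$labels, length(day$traj$contra))
    }
    expect_equal(nrow(sub$ground_truth$deltas),
                 nrow(sub$ground_truth$features))
  }
  # alternate hemisphere for the second subject, mirrored on projection
  s3 <- generate_study(synthetic_config(n_subjects = 2, days = 1,
                                        events_per_day = 3, n_channels = 4,
                                        neural_rate = 500, seed = 8))
  expect_equal(s3$subjects[[2]]$layout$hemisphere, "right")
  expect_true(all(s3$subjects[[2]]$layout$positions[, 1] > 0))
})
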