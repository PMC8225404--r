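# Movement-initiation detection and the pruning rules.

test_that("onset rule: 0.5 s contiguous rest then 0.5 s contiguous move", {
  st <- state_sequence(lab_runs(c(rest = 15, move = 15)))
  ev <- detect_onsets(st, 30)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_frame, 16)        # first move frame, 1-based
  expect_equal(ev$onset_time, 0.5)
  expect_equal(ev$duration, 0.5)

  expect_equal(nrow(detect_onsets(
    state_sequence(lab_runs(c(rest = 14, move = 15))), 30)), 0)
  expect_equal(nrow(detect_onsets(
    state_sequence(rep("rest", 100)), 30)), 0)
  expect_error(detect_onsets(st, 29), "integral")

  # duration equals the full move dwell containing the onset
  st2 <- state_sequence(lab_runs(c(rest = 30, move = 45, rest = 20,
                                   move = 15, rest = 15)))
  ev2 <- detect_onsets(st2, 30)
  expect_equal(ev2$onset_frame, c(31, 96))
  expect_equal(ev2$duration, c(1.5, 0.5))
})

test_that("quadratic fit R^2: parabola and line score 1, noise scores near 0, short dwell undefined", {
  tr <- make_traj(120, moves = data.frame(onset = 31, len = 60, mag = 80,
                                          angle_deg = 90))
  ev <- data.frame(onset_frame = 31, move_end_frame = 90)
  expect_equal(quad_fit_r2(tr, ev), 1, tolerance = 1e-10)

  # linear radial trace: outward drift at constant speed
  n <- 120
  x <- c(rep(100, 30), 100 + seq_len(60) * 2, rep(220, 30))
  tr_lin <- wrist_trajectory(x, rep(100, n))
  expect_equal(quad_fit_r2(tr_lin, ev), 1, tolerance = 1e-12)

  set.seed(2)
  tr_noise <- wrist_trajectory(100 + rnorm(400), 100 + rnorm(400))
  r2 <- quad_fit_r2(tr_noise, data.frame(onset_frame = 1,
                                         move_end_frame = 400))
  expect_lt(r2, 0.2)

  expect_warning(r2s <- quad_fit_r2(tr, data.frame(onset_frame = 31,
                                                   move_end_frame = 32)),
                 "undefined")
  expect_true(is.na(r2s))
})

test_that("pruning applies duration, confidence and quadratic rules with recorded reasons", {
  base <- data.frame(onset_frame = 1:10, onset_time = (1:10) * 10, day = 1,
                     clock_time = (1:10) * 10, duration = 1,
                     move_end_frame = 40, reach_magnitude = 50,
                     reach_angle_raw = 90, reach_angle = 90,
                     onset_speed = 10:1, mean_confidence = 0.9, quad_r2 = 0.9)
  base$duration[2] <- 4.5                  # too long
  base$mean_confidence[5] <- 0.3           # occluded
  base$quad_r2[8] <- 0.5                   # not parabolic
  pr <- prune_events(base)
  expect_equal(sum(pr$kept), 7)
  expect_equal(pr$reject_reason[c(2, 5, 8)],
               c("duration", "confidence", "quad_r2"))
  # boundary durations are kept (closed interval)
  b <- base[1, ]; b$duration <- 0.5
  expect_true(prune_events(b)$kept)
  b$duration <- 4
  expect_true(prune_events(b)$kept)
  # idempotence and order independence
  pr2 <- prune_events(pr[, names(base)])
  expect_equal(pr2$kept, pr$kept)
  shuf <- sample(nrow(base))
  pr3 <- prune_events(base[shuf, ])
  expect_equal(pr3$kept, pr$kept[shuf])
})

test_that("per-day cap keeps the 200 fastest with deterministic ties", {
  set.seed(31)
  n <- 250
  ev <- data.frame(onset_frame = seq_len(n), onset_time = seq_len(n) * 5,
                   day = 1, clock_time = seq_len(n) * 5, duration = 1,
                   move_end_frame = seq_len(n) + 30,
                   reach_magnitude = 50, reach_angle_raw = 90,
                   reach_angle = 90, onset_speed = sample(n),
                   mean_confidence = 0.9, quad_r2 = 0.9)
  pr <- prune_events(ev)
  expect_equal(sum(pr$kept), 200)
  expect_gte(min(pr$onset_speed[pr$kept]), max(pr$onset_speed[!pr$kept]))
  expect_true(all(pr$reject_reason[!pr$kept] == "day_cap"))
  # exact ties broken by earlier onset time
  ev$onset_speed <- rep(1, n)
  pr_tie <- prune_events(ev)
  expect_true(all(pr_tie$kept[1:200]))
  # cap applies per day, not globally
  ev$day <- rep(1:2, length.out = n)
  expect_equal(sum(prune_events(ev)$kept), n)
})

test_that("annotation computes reach kinematics in image coordinates (up = -y)", {
  tr <- make_traj(120, moves = data.frame(onset = 31, len = 45, mag = 60,
                                          angle_deg = 90))
  st <- state_sequence(lab_runs(c(rest = 30, move = 45, rest = 45)))
  ev <- find_events(st, tr)
  expect_equal(nrow(ev), 1)
  expect_true(ev$kept)
  expect_equal(ev$reach_magnitude, 60, tolerance = 0.02)
  expect_equal(ev$reach_angle, 90, tolerance = 1)     # upward reach
  expect_gt(ev$quad_r2, 0.99)
  # downward reach maps to -90
  tr_dn <- make_traj(120, moves = data.frame(onset = 31, len = 45, mag = 60,
                                             angle_deg = 270))
  ev_dn <- find_events(st, tr_dn)
  expect_equal(ev_dn$reach_angle, -90, tolerance = 1)
})

test_that("exclusion intervals drop events before pruning", {
  tr <- make_traj(240, moves = data.frame(onset = c(61, 181), len = 30,
                                          mag = 50, angle_deg = 90))
  st <- state_sequence(lab_runs(c(rest = 60, move = 30, rest = 90,
                                  move = 30, rest = 30)))
  ev_all <- find_events(st, tr)
  expect_equal(nrow(ev_all), 2)
  ev_ex <- find_events(st, tr, exclude = data.frame(start = 0, end = 3))
  expect_equal(nrow(ev_ex), 1)
  expect_equal(ev_ex$onset_frame, 181)
})

test_that("decoded onsets on near-noiseless synthetic data land within 2 frames of truth", {
  cfg <- synthetic_config(n_subjects = 1, days = 1, events_per_day = 12,
                          traj_noise_sd = 0.05, seed = 13)
  tr <- generate_trajectory(cfg, 1, 1, seed = 29)
  par <- suppressWarnings(fit_arhsmm(tr$contra, init_seed = 1, max_iter = 10,
                                     max_dwell = 150))
  dec <- decode_states(par, tr$contra)
  ev <- detect_onsets(dec, 30)
  truth <- tr$truth$onset_frame
  hits <- vapply(truth, function(tf) any(abs(ev$onset_frame - tf) <= 2), TRUE)
  expect_gte(mean(hits), 0.95)
})
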