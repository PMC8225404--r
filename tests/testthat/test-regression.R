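# Robust regression, forward selection, splits, feature importance.

# Feature table with controllable structure for design/selection tests.
sim_features <- function(n, days = 3, seed = 1) {
  set.seed(seed)
  data.frame(event_id = seq_len(n),
             day = sample(seq_len(days), n, replace = TRUE),
             time_of_day = sample(1:2, n, replace = TRUE),
             duration = rlnorm(n, 0, 0.4),
             magnitude = rlnorm(n, 4, 0.5),
             angle = c(-90, 90)[1 + rbinom(n, 1, 0.5)] + rnorm(n, 0, 10),
             onset_speed = rlnorm(n, 4.5, 0.4),
             speech_ratio = runif(n),
             bimanual_ratio = runif(n, 0, 0.7),
             bimanual_overlap = runif(n),
             bimanual_class = rbinom(n, 1, 0.4))
}

test_that("design matrix encodes, standardizes on training rows only, and flags degenerate input", {
  ft <- sim_features(200, days = 5)
  train <- 1:150
  d <- build_design(ft, train)
  expect_equal(length(d$blocks$day), 4)          # 5 days -> 4 dummies
  expect_equal(colnames(d$X)[1], "(Intercept)")
  for (f in c("angle", "duration", "onset_speed")) {
    expect_equal(mean(d$X[train, f]), 0, tolerance = 1e-12)
    expect_equal(sd(d$X[train, f]), 1, tolerance = 1e-12)
  }
  # log-then-standardize for duration/magnitude
  expect_equal(unname(d$center["duration"]), mean(log(ft$duration[train])))
  # no leakage: test rows use training statistics
  ft2 <- ft
  ft2$angle[151:200] <- ft2$angle[151:200] + 1000
  d2 <- build_design(ft2, train)
  expect_identical(d2$center, d$center)
  expect_identical(d2$scale, d$scale)
  expect_identical(d2$X[train, ], d$X[train, ])
  # constant continuous feature errors; single-level categorical drops
  ft3 <- ft; ft3$speech_ratio <- 0.5
  expect_error(build_design(ft3, train), "zero variance")
  ft4 <- ft; ft4$time_of_day <- 1
  expect_warning(d4 <- build_design(ft4, train), "single level")
  expect_null(d4$blocks$time_of_day)
})

test_that("Huber IRLS: exact on noiseless data, OLS in the large-delta limit, robust to outliers", {
  set.seed(11)
  n <- 150
  X <- cbind(1, matrix(rnorm(n * 3), n))
  colnames(X) <- c("(Intercept)", "a", "b", "c")
  beta <- c(2, -1, 0.5, 3)
  y0 <- as.numeric(X %*% beta)
  expect_equal(unname(huber_fit(X, y0)), beta, tolerance = 1e-6)
  y <- y0 + rnorm(n, 0, 0.5)
  ols <- unname(lm.fit(X, y)$coefficients)
  expect_equal(unname(huber_fit(X, y, delta = 1e8)), ols, tolerance = 1e-6)
  # agreement with the MASS IRLS implementation as an independent oracle
  hb <- huber_fit(X, y, delta = 1.345)
  rlm_fit <- MASS::rlm(X, y, k = 1.345, maxit = 100)
  expect_equal(unname(hb), unname(rlm_fit$coefficients), tolerance = 0.02)
  # gross outliers hurt the Huber fit less than OLS (seed majority)
  wins <- 0
  for (s in 1:7) {
    set.seed(100 + s)
    yo <- y0 + rnorm(n, 0, 0.5)
    out_idx <- sample(n, 15)
    yo[out_idx] <- yo[out_idx] + 40
    err_h <- sum((huber_fit(X, yo) - beta)^2)
    err_o <- sum((lm.fit(X, yo)$coefficients - beta)^2)
    wins <- wins + (err_h < err_o)
  }
  expect_gte(wins, 5)
  expect_error(huber_fit(X[, c(1, 2, 2)], y), "rank-deficient")
  expect_error(huber_fit(X[1:3, ], y[1:3]), "more rows")
})

test_that("forward selection retains truly predictive blocks and respects tie order", {
  ft <- sim_features(500, seed = 21)
  d <- build_design(ft)
  set.seed(22)
  y <- 2 * d$X[, "angle"] - 1.5 * d$X[, "onset_speed"] + rnorm(500, 0, 0.8)
  kept <- forward_select(d, y)
  expect_true(all(c("angle", "onset_speed") %in% kept))
  # the strongest feature enters first
  expect_equal(kept[1], "angle")
  # duplicated feature columns: only one of the pair is retained
  ft_dup <- ft
  ft_dup$bimanual_overlap <- ft_dup$speech_ratio
  d_dup <- build_design(ft_dup)
  y2 <- 3 * d_dup$X[, "speech_ratio"] + rnorm(500, 0, 0.5)
  kept2 <- forward_select(d_dup, y2)
  expect_equal(sum(c("speech_ratio", "bimanual_overlap") %in% kept2), 1)
  expect_true("speech_ratio" %in% kept2)       # earlier block wins the tie
})

test_that("shuffle importance is exactly zero under the identity permutation", {
  ft <- sim_features(200, seed = 31)
  d <- build_design(ft, 1:160)
  set.seed(32)
  y <- 1.5 * d$X[, "angle"] + rnorm(200, 0, 0.7)
  retained <- c("angle", "duration")
  cols <- c(1L, unlist(d$blocks[retained]))
  beta <- huber_fit(d$X[1:160, cols], y[1:160])
  full_r2 <- 1 - sum((y[161:200] - d$X[161:200, cols] %*% beta)^2) /
    sum((y[161:200] - mean(y[161:200]))^2)
  dr0 <- delta_r2(d, y, 1:160, 161:200, retained, "angle", full_r2,
                  perm = 1:160)
  expect_identical(dr0, 0)
  # shuffling the load-bearing feature costs real R^2
  set.seed(33)
  dr <- delta_r2(d, y, 1:160, 161:200, retained, "angle", full_r2,
                 perm = sample(160))
  expect_gt(dr, 0.2)
})

test_that("stratified splits take ~10% per day and never leak tiny days", {
  strat <- getFromNamespace("stratified_split", "naturalreach")
  days <- rep(1:3, c(50, 37, 13))
  set.seed(41)
  sp <- strat(days)
  for (d in 1:3) {
    nd <- sum(days == d)
    expect_equal(sum(days[sp$test] == d), max(1, round(0.1 * nd)))
  }
  expect_setequal(c(sp$train, sp$test), seq_along(days))
  expect_length(intersect(sp$train, sp$test), 0)
  # a day with one event stays in training, with a warning
  expect_warning(sp2 <- strat(c(rep(1, 30), 2)), "fewer than 2")
  expect_true(31 %in% sp2$train)
})

test_that("run_splits is deterministic, averages over exactly n_splits, and recovers planted effects", {
  ft <- sim_features(240, seed = 51)
  d <- build_design(ft)
  set.seed(52)
  y <- -0.8 * d$X[, "angle"] + 0.4 * (ft$day == 2) + rnorm(240, 0, 0.5)
  bp <- data.frame(event_id = ft$event_id, channel = 1, LFB = y, HFB = -y)
  r1 <- run_splits(bp, ft, n_splits = 12, seed = 99)
  r2 <- run_splits(bp, ft, n_splits = 12, seed = 99)
  expect_identical(r1$coefficients, r2$coefficients)
  expect_identical(r1$delta_r2, r2$delta_r2)
  expect_equal(r1$n_splits, 12)
  expect_length(r1$standardization, 12)
  co <- r1$coefficients
  expect_equal(co$coef[co$band == "LFB" & co$term == "angle"], -0.8,
               tolerance = 0.12)
  expect_equal(co$coef[co$band == "HFB" & co$term == "angle"], 0.8,
               tolerance = 0.12)
  dr <- r1$delta_r2
  for (b in c("LFB", "HFB")) {
    db <- dr[dr$band == b, ]
    expect_equal(db$feature[which.max(db$delta_r2)], "angle")
  }
  expect_error(run_splits(bp[1:10, ], ft[1:10, ]), "at least 20")
})
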