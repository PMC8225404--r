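# Behavioral segmentation: AR-HSMM engine, EM fitting, decoding.

engine <- function(name) getFromNamespace(name, "naturalreach")

test_that("Viterbi decoding equals the exhaustive-enumeration oracle on short sequences", {
  dwell_log_tables <- engine("dwell_log_tables")
  viterbi <- engine("hsmm_viterbi_engine")
  enumerate <- engine("hsmm_enumerate_best")
  set.seed(421)
  for (case in 1:80) {
    n <- sample(2:11, 1)
    D <- sample(2:6, 1)
    lb <- matrix(rnorm(n * 2, sd = 2), n, 2)
    lt <- dwell_log_tables(random_dwell(), D)
    lpi <- log(c(0.4, 0.6))
    v <- viterbi(lb, lt$lp, lt$lsurv, lpi)
    e <- enumerate(lb, lt$lp, lt$lsurv, lpi)
    expect_equal(attr(v, "score"), e$score, tolerance = 1e-10)
    expect_identical(as.integer(v), e$path)
  }
})

test_that("forward pass likelihood and state posteriors match brute-force enumeration", {
  dwell_log_tables <- engine("dwell_log_tables")
  forward <- engine("hsmm_forward")
  estep <- engine("hsmm_estep")
  compositions <- function(n) {
    if (n == 0) return(list(integer(0)))
    do.call(c, lapply(seq_len(n), function(f)
      lapply(compositions(n - f), function(r) c(f, r))))
  }
  set.seed(77)
  for (case in 1:15) {
    n <- sample(3:8, 1)
    D <- sample(2:5, 1)
    lb <- matrix(rnorm(n * 2, sd = 1.5), n, 2)
    lt <- dwell_log_tables(random_dwell(), D)
    lpi <- log(c(0.5, 0.5))
    # brute force: score every alternating segmentation
    Cum <- rbind(0, apply(lb, 2, cumsum))
    scs <- c(); paths <- list()
    for (durs in compositions(n)) for (s1 in 1:2) {
      s <- s1; t0 <- 0; sc <- lpi[s1]; ok <- TRUE; K <- length(durs)
      st <- integer(0)
      for (j in seq_len(K)) {
        d <- durs[j]
        if (d > D) { ok <- FALSE; break }
        sc <- sc + (if (j < K) lt$lp[d, s] else lt$lsurv[d, s]) +
          Cum[t0 + d + 1, s] - Cum[t0 + 1, s]
        st <- c(st, rep(s, d)); t0 <- t0 + d; s <- 3 - s
      }
      if (ok) { scs <- c(scs, sc); paths[[length(paths) + 1]] <- st }
    }
    L <- max(scs) + log(sum(exp(scs - max(scs))))
    fwd <- forward(lb, lt$lp, lt$lsurv, lpi)
    expect_equal(fwd$loglik, L, tolerance = 1e-9)
    w <- exp(scs - L)
    post <- matrix(0, n, 2)
    for (i in seq_along(paths)) for (t in 1:n)
      post[t, paths[[i]][t]] <- post[t, paths[[i]][t]] + w[i]
    es <- estep(lb, lt$lp, lt$lsurv, lpi)
    expect_equal(es$gamma, post, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("EM recovers innovation variances, increases log-likelihood, and relabels rest first", {
  # simulate straight from the model: rest = tight AR, move = loose
  set.seed(5)
  n <- 3000
  z <- matrix(0, n, 2)
  lab <- integer(n)
  s <- 1; t0 <- 0
  sig <- c(0.15, 2)
  while (t0 < n) {
    d <- 1 + rnbinom(1, size = 5, mu = if (s == 1) 50 else 35)
    idx <- (t0 + 1):min(t0 + d, n)
    z[idx, ] <- matrix(rnorm(2 * length(idx), 0, sig[s]), ncol = 2)
    lab[idx] <- s
    t0 <- t0 + d
    s <- 3 - s
  }
  pos <- apply(z, 2, cumsum)
  traj <- wrist_trajectory(100 + pos[, 1], 100 + pos[, 2])
  fit <- fit_arhsmm(traj, init_seed = 2, max_iter = 15, max_dwell = 120)
  tr <- attr(fit, "loglik_trace")
  expect_true(all(diff(tr) > -1e-6 * abs(tr[-length(tr)])))
  expect_lt(sum(diag(fit$Sigma[[1]])), sum(diag(fit$Sigma[[2]])))
  for (st in 1:2)
    expect_equal(sum(diag(fit$Sigma[[st]])), 2 * sig[st]^2, tolerance = 0.2)
  # decoding tracks the generating labels (displacement t -> frame t+1)
  dec <- decode_states(fit, traj)
  expect_gt(mean(dec$labels[-1] == c("rest", "move")[lab[-n]]), 0.9)
})

test_that("degenerate and short inputs error; same seed gives identical fits", {
  const <- wrist_trajectory(rep(5, 300), rep(7, 300))
  expect_error(fit_arhsmm(const), "singular")
  expect_error(fit_arhsmm(make_traj(50, noise = 1)), "at least 200 frames")
  traj <- make_traj(400, moves = data.frame(onset = c(100, 300),
                                            len = 40, mag = 50,
                                            angle_deg = 90), noise = 0.5)
  f1 <- suppressWarnings(fit_arhsmm(traj, init_seed = 3, max_iter = 5,
                                    max_dwell = 80))
  f2 <- suppressWarnings(fit_arhsmm(traj, init_seed = 3, max_iter = 5,
                                    max_dwell = 80))
  expect_identical(f1$A, f2$A)
  expect_identical(f1$dwell, f2$dwell)
  expect_error(decode_states(f1, make_traj(1, noise = 0)), "shorter")
})

test_that("decoding is near-noiseless-exact and local", {
  # hand-built parameters with well-separated states
  par <- hsmm_params(
    A = list(matrix(0, 2, 2), matrix(0, 2, 2)),
    Sigma = list(diag(0.05, 2), diag(9, 2)),
    dwell = list(list(size = 5, mean = 50), list(size = 5, mean = 30)),
    max_dwell = 100)
  traj <- make_traj(240, moves = data.frame(onset = 91, len = 30, mag = 60,
                                            angle_deg = 90), noise = 0.05,
                    seed = 9)
  dec <- decode_states(par, traj)
  truth <- lab_runs(c(rest = 90, move = 30, rest = 120))
  expect_gt(mean(dec$labels == truth), 0.97)
  # appending a long rest tail leaves early labels unchanged
  traj2 <- wrist_trajectory(c(traj$x, rep(100, 150)), c(traj$y, rep(100, 150)))
  dec2 <- decode_states(par, traj2)
  expect_identical(dec2$labels[1:120], dec$labels[1:120])
})

test_that("label-swap symmetry: initialization permutation does not change decoded states", {
  traj <- make_traj(600, moves = data.frame(onset = c(100, 300, 500),
                                            len = 40, mag = 60,
                                            angle_deg = c(90, 270, 45)),
                    noise = 0.4, seed = 4)
  f1 <- suppressWarnings(fit_arhsmm(traj, init_seed = 1, max_iter = 8,
                                    max_dwell = 80))
  f2 <- suppressWarnings(fit_arhsmm(traj, init_seed = 8, max_iter = 8,
                                    max_dwell = 80))
  expect_lt(sum(diag(f1$Sigma[[1]])), sum(diag(f1$Sigma[[2]])))
  expect_lt(sum(diag(f2$Sigma[[1]])), sum(diag(f2$Sigma[[2]])))
  d1 <- decode_states(f1, traj)
  d2 <- decode_states(f2, traj)
  expect_gt(mean(d1$labels == d2$labels), 0.95)
})
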