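# Two-state (rest/move) first-order autoregressive hidden semi-Markov model
# on per-frame wrist displacement vectors.
#
# States strictly alternate (the 2-state transition matrix is the swap), so
# the model is fully described by per-state AR(1) observation parameters, a
# per-state dwell distribution (negative binomial on {1, 2, ...}, truncated
# at max_dwell), and initial state probabilities. The final dwell of a
# sequence is treated as right-censored: its duration term uses the survivor
# function P(dwell >= observed length).

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(v - m)))
}

other_state <- function(s) 3L - s

#' AR-HSMM parameter set
#'
#' @param A list of two 2x2 AR coefficient matrices (rest, move).
#' @param Sigma list of two 2x2 innovation covariance matrices.
#' @param dwell list of two lists with elements `size` and `mean` (negative
#'   binomial on dwell - 1; `mean` is the mean dwell in frames, > 1).
#' @param pi initial state probabilities (rest, move).
#' @param max_dwell truncation of the dwell support (frames).
#' @return object of class `hsmm_params`.
#' @export
hsmm_params <- function(A, Sigma, dwell, pi = c(0.5, 0.5), max_dwell = 150) {
  for (s in 1:2) {
    if (any(!is.finite(A[[s]])) || any(!is.finite(Sigma[[s]])))
      stop("non-finite HSMM parameters")
    ev <- eigen(Sigma[[s]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("innovation covariance must be positive definite")
    if (dwell[[s]]$size <= 0 || dwell[[s]]$mean <= 1)
      stop("dwell parameters must give size > 0 and mean dwell > 1 frame")
  }
  if (abs(sum(pi) - 1) > 1e-8 || any(pi < 0)) stop("pi must be a distribution")
  structure(list(A = A, Sigma = Sigma, dwell = dwell, pi = pi,
                 max_dwell = as.integer(max_dwell), loglik = NA_real_),
            class = "hsmm_params")
}

#' @export
print.hsmm_params <- function(x, ...) {
  cat(sprintf(
    "<hsmm_params: innov trace rest %.3g / move %.3g, mean dwell %.1f / %.1f, ll %.2f>\n",
    sum(diag(x$Sigma[[1]])), sum(diag(x$Sigma[[2]])),
    x$dwell[[1]]$mean, x$dwell[[2]]$mean, x$loglik))
  invisible(x)
}

# Truncated dwell log-pmf (max_dwell x 2) and log-survivor matrices.
dwell_log_tables <- function(dwell, max_dwell) {
  lp <- matrix(-Inf, max_dwell, 2)
  for (s in 1:2) {
    raw <- stats::dnbinom(0:(max_dwell - 1), size = dwell[[s]]$size,
                          mu = dwell[[s]]$mean - 1, log = TRUE)
    lp[, s] <- raw - logsumexp(raw)
  }
  # lsurv[d, s] = log P(dwell >= d) under the truncated pmf
  lsurv <- apply(lp, 2, function(col) {
    rev(log(cumsum(rev(exp(col)))))
  })
  lsurv <- pmin(lsurv, 0)
  list(lp = lp, lsurv = lsurv)
}

# Displacement (velocity) observations from a trajectory: z_t = pos_{t+1} -
# pos_t. The HSMM runs on these n = T - 1 vectors; frame labels are mapped
# back with frame 1 taking the first displacement's label.
traj_displacements <- function(traj) {
  cbind(diff(traj$x), diff(traj$y))
}

# Per-observation log density under each state: N(z_t; A_s z_{t-1}, Sigma_s),
# z_0 = 0. Returns n x 2 matrix.
ar_obs_loglik <- function(z, A, Sigma) {
  n <- nrow(z)
  zprev <- rbind(c(0, 0), z[-n, , drop = FALSE])
  out <- matrix(0, n, 2)
  for (s in 1:2) {
    mu <- zprev %*% t(A[[s]])
    r <- z - mu
    Sinv <- solve(Sigma[[s]])
    q <- rowSums((r %*% Sinv) * r)
    out[, s] <- -log(2 * pi) - 0.5 * determinant(Sigma[[s]])$modulus[1] - 0.5 * q
  }
  out
}

# Segment-based forward pass with right-censored final dwell.
# lb: n x 2 log obs densities; returns list(alpha = n x 2, loglik).
hsmm_forward <- function(lb, lp, lsurv, lpi) {
  n <- nrow(lb)
  D <- nrow(lp)
  Cum <- rbind(0, apply(lb, 2, cumsum))          # Cum[t + 1, s] = sum lb[1..t, s]
  alpha <- matrix(-Inf, n, 2)
  for (t in seq_len(n)) {
    dmax <- min(D, t)
    d <- seq_len(dmax)
    for (s in 1:2) {
      seg <- Cum[t + 1, s] - Cum[t - d + 1, s]
      prev <- numeric(dmax)
      td <- t - d
      pos <- td >= 1
      prev[pos] <- alpha[td[pos], other_state(s)]
      prev[!pos] <- lpi[s]
      alpha[t, s] <- logsumexp(prev + lp[d, s] + seg)
    }
  }
  # censored likelihood: last segment covers n - d + 1 .. n with dwell >= d
  terms <- numeric(0)
  for (s in 1:2) {
    dmax <- min(D, n)
    d <- seq_len(dmax)
    seg <- Cum[n + 1, s] - Cum[n - d + 1, s]
    td <- n - d
    prev <- numeric(dmax)
    pos <- td >= 1
    prev[pos] <- alpha[td[pos], other_state(s)]
    prev[!pos] <- lpi[s]
    terms <- c(terms, prev + lsurv[d, s] + seg)
  }
  list(alpha = alpha, loglik = logsumexp(terms))
}

# Backward pass: beta[t, s] = log P(obs t+1..n | segment of state s ends at t).
hsmm_backward <- function(lb, lp, lsurv) {
  n <- nrow(lb)
  D <- nrow(lp)
  Cum <- rbind(0, apply(lb, 2, cumsum))
  beta <- matrix(-Inf, n, 2)
  for (t in (n - 1):1) {
    if (t < 1) break
    for (s in 1:2) {
      o <- other_state(s)
      dmax <- min(D, n - t)
      d <- seq_len(dmax)
      seg <- Cum[t + d + 1, o] - Cum[t + 1, o]
      ends <- t + d
      val <- lp[d, o] + seg
      inner <- ends < n
      val[inner] <- val[inner] + beta[ends[inner], o]
      val[!inner] <- lsurv[d[!inner], o] + seg[!inner]
      beta[t, s] <- logsumexp(val)
    }
  }
  beta
}

# E-step quantities: per-frame state posteriors gamma (n x 2), expected
# complete-dwell counts (D x 2), and first-segment state posterior.
hsmm_estep <- function(lb, lp, lsurv, lpi) {
  n <- nrow(lb)
  D <- nrow(lp)
  fwd <- hsmm_forward(lb, lp, lsurv, lpi)
  alpha <- fwd$alpha
  L <- fwd$loglik
  beta <- hsmm_backward(lb, lp, lsurv)
  Cum <- rbind(0, apply(lb, 2, cumsum))
  dgamma <- matrix(0, n + 1, 2)      # difference-array accumulator
  dur_counts <- matrix(0, D, 2)
  cens_counts <- matrix(0, D, 2)     # right-censored final segments
  first_post <- c(0, 0)
  for (b in seq_len(n)) {
    dmax <- min(D, b)
    d <- seq_len(dmax)
    a <- b - d + 1
    for (s in 1:2) {
      seg <- Cum[b + 1, s] - Cum[a, s]
      prev <- numeric(dmax)
      pos <- a > 1
      prev[pos] <- alpha[a[pos] - 1, other_state(s)]
      prev[!pos] <- lpi[s]
      if (b < n) {
        logw <- prev + lp[d, s] + seg + beta[b, s]
      } else {
        logw <- prev + lsurv[d, s] + seg
      }
      w <- exp(logw - L)
      keep <- w > 0
      if (!any(keep)) next
      dgamma[a[keep], s] <- dgamma[a[keep], s] + w[keep]
      dgamma[b + 1, s] <- dgamma[b + 1, s] - sum(w[keep])
      if (b < n) {
        dur_counts[d[keep], s] <- dur_counts[d[keep], s] + w[keep]
      } else {
        cens_counts[d[keep], s] <- cens_counts[d[keep], s] + w[keep]
      }
      fk <- keep & (a == 1)
      if (any(fk)) first_post[s] <- first_post[s] + sum(w[fk])
    }
  }
  gamma <- apply(dgamma[seq_len(n), , drop = FALSE], 2, cumsum)
  gamma <- pmax(gamma, 0)
  gamma <- gamma / pmax(rowSums(gamma), .Machine$double.eps)
  list(gamma = gamma, dur_counts = dur_counts, cens_counts = cens_counts,
       first_post = first_post, loglik = L)
}

# Weighted truncated-NB fit of a dwell distribution from expected counts of
# complete segments (wd) and right-censored final segments (cw, entering
# through the survivor function).
fit_dwell_nb <- function(wd, start, cw = NULL) {
  d <- which(wd > 0)
  if (length(d) == 0) return(start)
  w <- wd[d]
  D <- length(wd)
  dc <- if (is.null(cw)) integer(0) else which(cw > 0)
  wc <- if (is.null(cw)) numeric(0) else cw[dc]
  nll <- function(par) {
    size <- exp(par[1]); mu <- exp(par[2])
    # box constraints: shifted dwells can be under-dispersed (variance
    # below mean), which no NB represents; unbounded optimization then
    # escapes to degenerate truncated shapes with absurd parameters
    if (size < 1e-2 || size > 1e4 || mu > 3 * D) return(1e12)
    lp <- stats::dnbinom(0:(D - 1), size = size, mu = mu, log = TRUE)
    lz <- logsumexp(lp)
    lp <- lp - lz
    val <- -sum(w * lp[d])
    if (length(dc) > 0) {
      ls <- rev(log(cumsum(rev(exp(lp)))))
      val <- val - sum(wc * pmin(ls[dc], 0))
    }
    val
  }
  p0 <- c(log(start$size), log(max(start$mean - 1, 1e-3)))
  fit <- tryCatch(stats::optim(p0, nll, method = "Nelder-Mead",
                               control = list(maxit = 200)),
                  error = function(e) NULL)
  if (is.null(fit) || fit$value > nll(p0) + 1e-9) return(start)
  list(size = exp(fit$par[1]), mean = 1 + exp(fit$par[2]))
}

# Weighted AR(1) M-step for one state.
fit_ar_state <- function(z, gamma_s) {
  n <- nrow(z)
  zprev <- rbind(c(0, 0), z[-n, , drop = FALSE])
  W <- gamma_s
  Sxx <- crossprod(zprev * W, zprev) + diag(1e-10, 2)
  Sxy <- crossprod(zprev * W, z)
  A <- t(solve(Sxx, Sxy))
  r <- z - zprev %*% t(A)
  Sig <- crossprod(r * W, r) / max(sum(W), .Machine$double.eps)
  Sig <- Sig + diag(1e-9, 2)
  list(A = A, Sigma = Sig)
}

#' Fit the two-state AR-HSMM by expectation-maximization
#'
#' Initialization is 2-means on frame speed (rest = the lower-speed cluster)
#' under a fixed seed; the E-step uses exact segment-based forward-backward
#' with a right-censored final dwell, and the M-step refits the per-state
#' AR(1) observation model by weighted least squares and the negative
#' binomial dwell laws by weighted maximum likelihood. The observed-data
#' log-likelihood is non-decreasing across iterations (up to numerical
#' tolerance). On return states are relabeled so that 'rest' is the state
#' with the smaller innovation-covariance trace.
#'
#' @param traj a [wrist_trajectory()]; low-confidence gaps should already be
#'   interpolated (confidence is used later for event pruning, not here).
#' @param init_seed seed for the clustering initialization.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_dwell dwell truncation in frames.
#' @return fitted [hsmm_params()] with attributes `loglik_trace`.
#' @export
fit_arhsmm <- function(traj, init_seed = 1, max_iter = 30, tol = 1e-5,
                       max_dwell = 150) {
  stopifnot(inherits(traj, "wrist_trajectory"))
  if (length(traj) < 200) stop("need at least 200 frames to fit")
  if (any(!is.finite(traj$x)) || any(!is.finite(traj$y)))
    stop("non-finite positions; interpolate before fitting")
  z <- traj_displacements(traj)
  speed <- sqrt(rowSums(z^2))
  if (stats::sd(speed) < 1e-10)
    stop("singular model: trajectory is (near) constant")
  # --- initialization: 2-means on speed -------------------------------------
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(init_seed)
  km <- stats::kmeans(speed, centers = 2, nstart = 5)
  rest_cl <- which.min(km$centers)
  lab <- ifelse(km$cluster == rest_cl, 1L, 2L)
  gamma0 <- cbind(lab == 1L, lab == 2L) * 1
  par <- list(A = vector("list", 2), Sigma = vector("list", 2),
              dwell = vector("list", 2), pi = c(0.5, 0.5))
  for (s in 1:2) {
    fs <- fit_ar_state(z, gamma0[, s])
    par$A[[s]] <- fs$A
    par$Sigma[[s]] <- fs$Sigma
    runs <- rle(lab)
    dd <- runs$lengths[runs$values == s]
    m <- max(mean(dd), 2)
    v <- max(stats::var(dd), 1e-3)
    size <- if (v > m - 1) (m - 1)^2 / (v - (m - 1)) else 50
    par$dwell[[s]] <- list(size = min(max(size, 0.1), 100), mean = m)
  }
  par$pi <- c(0.5, 0.5)
  # --- EM -------------------------------------------------------------------
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lt <- dwell_log_tables(par$dwell, max_dwell)
    lb <- ar_obs_loglik(z, par$A, par$Sigma)
    es <- hsmm_estep(lb, lt$lp, lt$lsurv, log(par$pi))
    ll_trace <- c(ll_trace, es$loglik)
    if (is.finite(ll_prev) && es$loglik < ll_prev - 1e-6 * abs(ll_prev)) {
      warning("log-likelihood decreased numerically; stopping")
      break
    }
    if (is.finite(ll_prev) && abs(es$loglik - ll_prev) < tol * abs(ll_prev)) {
      ll_prev <- es$loglik
      converged <- TRUE
      break
    }
    ll_prev <- es$loglik
    for (s in 1:2) {
      fs <- fit_ar_state(z, es$gamma[, s])
      par$A[[s]] <- fs$A
      par$Sigma[[s]] <- fs$Sigma
      par$dwell[[s]] <- fit_dwell_nb(es$dur_counts[, s], par$dwell[[s]],
                                     es$cens_counts[, s])
    }
    fp <- es$first_post / max(sum(es$first_post), .Machine$double.eps)
    if (sum(fp) > 0) par$pi <- fp            # exact M-step maximizer
    if (min(vapply(par$Sigma, function(S) det(S), 1)) < 1e-24)
      stop("singular model: innovation covariance collapsed")
  }
  if (!converged && length(ll_trace) == max_iter)
    warning("EM did not converge in max_iter iterations; returning best iterate")
  # --- relabel so state 1 = rest (smaller innovation trace) -----------------
  if (sum(diag(par$Sigma[[1]])) > sum(diag(par$Sigma[[2]]))) {
    par$A <- rev(par$A)
    par$Sigma <- rev(par$Sigma)
    par$dwell <- rev(par$dwell)
    par$pi <- rev(par$pi)
  }
  out <- hsmm_params(par$A, par$Sigma, par$dwell, par$pi, max_dwell)
  out$loglik <- ll_prev
  attr(out, "loglik_trace") <- ll_trace
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Duration-explicit Viterbi on a log-observation matrix. Returns integer
# state path (length n). Exposed internally so tests can compare against an
# exhaustive-enumeration oracle on short sequences.
hsmm_viterbi_engine <- function(lb, lp, lsurv, lpi) {
  n <- nrow(lb)
  D <- nrow(lp)
  Cum <- rbind(0, apply(lb, 2, cumsum))
  V <- matrix(-Inf, n, 2)
  back_d <- matrix(0L, n, 2)
  for (t in seq_len(n)) {
    dmax <- min(D, t)
    d <- seq_len(dmax)
    for (s in 1:2) {
      seg <- Cum[t + 1, s] - Cum[t - d + 1, s]
      td <- t - d
      prev <- numeric(dmax)
      pos <- td >= 1
      prev[pos] <- V[td[pos], other_state(s)]
      prev[!pos] <- lpi[s]
      sc <- prev + lp[d, s] + seg
      k <- which.max(sc)
      V[t, s] <- sc[k]
      back_d[t, s] <- d[k]
    }
  }
  # censored final segment
  best <- c(-Inf, 0L, 0L)  # score, state, duration
  for (s in 1:2) {
    dmax <- min(D, n)
    d <- seq_len(dmax)
    seg <- Cum[n + 1, s] - Cum[n - d + 1, s]
    td <- n - d
    prev <- numeric(dmax)
    pos <- td >= 1
    prev[pos] <- V[td[pos], other_state(s)]
    prev[!pos] <- lpi[s]
    sc <- prev + lsurv[d, s] + seg
    k <- which.max(sc)
    if (sc[k] > best[1]) best <- c(sc[k], s, d[k])
  }
  path <- integer(n)
  t <- n
  s <- as.integer(best[2])
  d <- as.integer(best[3])
  path[(t - d + 1):t] <- s
  t <- t - d
  s <- other_state(s)
  while (t > 0) {
    d <- back_d[t, s]
    path[(t - d + 1):t] <- s
    t <- t - d
    s <- other_state(s)
  }
  attr(path, "score") <- best[1]
  path
}

# Exhaustive enumeration oracle over all alternating segmentations (tests).
hsmm_enumerate_best <- function(lb, lp, lsurv, lpi) {
  n <- nrow(lb)
  D <- nrow(lp)
  Cum <- rbind(0, apply(lb, 2, cumsum))
  best <- list(score = -Inf, path = NULL)
  score_path <- function(durs, s1) {
    states <- integer(0)
    s <- s1
    sc <- lpi[s1]
    t <- 0
    K <- length(durs)
    for (j in seq_len(K)) {
      d <- durs[j]
      if (d > D) return(NULL)
      sc <- sc + (if (j < K) lp[d, s] else lsurv[d, s]) +
        Cum[t + d + 1, s] - Cum[t + 1, s]
      states <- c(states, rep(s, d))
      t <- t + d
      s <- other_state(s)
    }
    list(score = sc, path = states)
  }
  compositions <- function(n) {
    if (n == 0) return(list(integer(0)))
    out <- list()
    for (first in seq_len(n)) {
      for (rest in compositions(n - first)) out[[length(out) + 1]] <- c(first, rest)
    }
    out
  }
  for (durs in compositions(n)) {
    for (s1 in 1:2) {
      r <- score_path(durs, s1)
      if (!is.null(r) && r$score > best$score) best <- r
    }
  }
  best
}

#' Decode the most likely move/rest segmentation
#'
#' Maximum a posteriori segmentation by duration-explicit Viterbi under the
#' alternating semi-Markov model, with per-frame posteriors from the exact
#' forward-backward pass attached as decode confidence.
#'
#' @param params fitted [hsmm_params()].
#' @param traj a [wrist_trajectory()].
#' @return a [state_sequence()] of the same length as the trajectory.
#' @export
decode_states <- function(params, traj) {
  stopifnot(inherits(params, "hsmm_params"), inherits(traj, "wrist_trajectory"))
  if (length(traj) < 2) stop("trajectory shorter than minimal dwell support")
  z <- traj_displacements(traj)
  lt <- dwell_log_tables(params$dwell, params$max_dwell)
  lb <- ar_obs_loglik(z, params$A, params$Sigma)
  lpi <- log(params$pi + 1e-300)
  path <- hsmm_viterbi_engine(lb, lt$lp, lt$lsurv, lpi)
  es <- hsmm_estep(lb, lt$lp, lt$lsurv, lpi)
  post <- es$gamma[cbind(seq_along(path), path)]
  labels <- c("rest", "move")[c(path[1], path)]   # frame 1 <- first displacement
  state_sequence(labels, posterior = c(post[1], post), source = "fitted")
}
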