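# Event-by-event regression of band power on behavioral features: robust
# (Huber) linear fits per electrode and band, forward selection by OLS
# adjusted R^2, repeated day-balanced train/test splits, and shuffle-based
# delta-R^2 feature importance.

continuous_features <- c("duration", "magnitude", "angle", "onset_speed",
                         "speech_ratio", "bimanual_ratio", "bimanual_overlap",
                         "bimanual_class")
log_features <- c("duration", "magnitude")
categorical_features <- c("day", "time_of_day")

#' Build the regression design matrix
#'
#' Continuous features are standardized (duration and magnitude
#' log-transformed first) using statistics from the training rows only; day
#' and time-of-day are one-hot encoded with one reference level dropped and
#' left unstandardized. An intercept column is included.
#'
#' @param ft feature table from [feature_table()].
#' @param train_idx row indices supplying the standardization statistics and
#'   categorical levels (default: all rows).
#' @return list with `X` (rows x columns incl. intercept), `blocks` (named
#'   list of column indices per feature), `center`, `scale`.
#' @export
build_design <- function(ft, train_idx = seq_len(nrow(ft))) {
  cols <- list(`(Intercept)` = matrix(1, nrow(ft), 1))
  blocks <- list()
  center <- numeric(0)
  scale <- numeric(0)
  for (f in continuous_features) {
    v <- ft[[f]]
    if (f %in% log_features) v <- log(pmax(v, 1e-12))
    mu <- mean(v[train_idx])
    sdv <- stats::sd(v[train_idx])
    if (!is.finite(sdv) || sdv < 1e-12)
      stop("feature '", f, "' has zero variance on the training rows")
    cols[[f]] <- matrix((v - mu) / sdv, ncol = 1,
                        dimnames = list(NULL, f))
    center[f] <- mu
    scale[f] <- sdv
  }
  for (f in categorical_features) {
    lev <- sort(unique(ft[[f]][train_idx]))
    if (length(lev) < 2) {
      warning("categorical feature '", f, "' has a single level; dropped")
      next
    }
    dm <- vapply(lev[-1], function(l) as.numeric(ft[[f]] == l),
                 numeric(nrow(ft)))
    colnames(dm) <- paste0(f, ".", lev[-1])
    cols[[f]] <- dm
  }
  X <- do.call(cbind, cols)
  colnames(X)[1] <- "(Intercept)"
  k <- 1
  for (nm in names(cols)[-1]) {
    w <- ncol(cols[[nm]])
    blocks[[nm]] <- (k + 1):(k + w)
    k <- k + w
  }
  list(X = X, blocks = blocks, center = center, scale = scale)
}

#' Huber-loss linear regression via IRLS
#'
#' Minimizes the Huber norm of residuals (quadratic within `delta` robust
#' scale units, linear beyond) by iteratively reweighted least squares with
#' MAD residual scale, converging coefficients to `tol`. As `delta` grows
#' the fit reproduces ordinary least squares.
#'
#' @param X design matrix (rows > columns, full rank).
#' @param y response.
#' @param delta Huber threshold in robust scale units (default 1.345, the
#'   standard 95%-efficiency choice).
#' @param max_iter,tol IRLS controls.
#' @return coefficient vector named by the design columns.
#' @export
huber_fit <- function(X, y, delta = 1.345, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X)) stop("need more rows than columns")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  beta <- stats::lm.fit(X, y)$coefficients
  for (it in seq_len(max_iter)) {
    r <- y - X %*% beta
    s <- stats::median(abs(r - stats::median(r))) / 0.6745
    if (s < 1e-12) break                     # (near-)interpolating fit
    u <- abs(r / s)
    w <- ifelse(u <= delta, 1, delta / u)
    beta_new <- stats::lm.wfit(X, y, as.numeric(w))$coefficients
    if (max(abs(beta_new - beta)) < tol * max(1, max(abs(beta)))) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  stats::setNames(as.numeric(beta), colnames(X))
}

r2_score <- function(y, yhat) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot < 1e-300) return(0)
  1 - sum((y - yhat)^2) / ss_tot
}

adj_r2 <- function(y, yhat, p) {
  n <- length(y)
  1 - (1 - r2_score(y, yhat)) * (n - 1) / (n - p - 1)
}

#' Greedy forward selection by OLS adjusted R^2
#'
#' Starting from the intercept-only model, repeatedly adds the feature block
#' whose inclusion yields the largest positive gain in adjusted R^2 of an
#' ordinary least-squares fit, stopping when no block improves it.
#' Categorical blocks enter atomically; ties are broken by block order.
#'
#' @param design output of [build_design()].
#' @param y response (training rows).
#' @param rows training row indices.
#' @return character vector of retained feature names (possibly empty).
#' @export
forward_select <- function(design, y, rows = seq_along(y)) {
  Xall <- design$X[rows, , drop = FALSE]
  yt <- y
  retained <- character(0)
  current_cols <- 1L                       # intercept
  best_adj <- adj_r2(yt, rep(mean(yt), length(yt)), 0)
  candidates <- names(design$blocks)
  repeat {
    gains <- rep(-Inf, length(candidates))
    for (i in seq_along(candidates)) {
      cols <- c(current_cols, design$blocks[[candidates[i]]])
      Xc <- Xall[, cols, drop = FALSE]
      if (qr(Xc)$rank < ncol(Xc)) next
      fit <- stats::lm.fit(Xc, yt)
      gains[i] <- adj_r2(yt, Xc %*% fit$coefficients, ncol(Xc) - 1)
    }
    if (length(candidates) == 0 || max(gains) <= best_adj + 1e-12) break
    k <- which.max(gains)
    best_adj <- gains[k]
    retained <- c(retained, candidates[k])
    current_cols <- c(current_cols, design$blocks[[candidates[k]]])
    candidates <- candidates[-k]
  }
  retained
}

#' Shuffle-based feature importance for one fitted model
#'
#' Permutes the training values of one retained feature (all columns of its
#' block with the same permutation), refits the Huber model on the retained
#' feature set, and evaluates R^2 on the untouched withheld rows; the
#' difference from the full-model R^2 is that feature's delta R^2. An
#' identity permutation gives exactly 0.
#'
#' @param design output of [build_design()].
#' @param y response over all rows.
#' @param train_rows,test_rows row index vectors.
#' @param retained retained feature names (must include `feature`).
#' @param feature the feature to shuffle.
#' @param full_r2 full-model R^2 on the withheld rows.
#' @param perm permutation of `seq_along(train_rows)`.
#' @param delta Huber threshold.
#' @return delta R^2 (full minus shuffled).
#' @export
delta_r2 <- function(design, y, train_rows, test_rows, retained, feature,
                     full_r2, perm, delta = 1.345) {
  stopifnot(feature %in% retained)
  cols <- c(1L, unlist(design$blocks[retained], use.names = FALSE))
  Xtr <- design$X[train_rows, cols, drop = FALSE]
  fcols_global <- design$blocks[[feature]]
  fcols <- match(fcols_global, cols)
  Xtr[, fcols] <- Xtr[perm, fcols, drop = FALSE]
  beta <- huber_fit(Xtr, y[train_rows], delta = delta)
  Xte <- design$X[test_rows, cols, drop = FALSE]
  shuf_r2 <- r2_score(y[test_rows], as.numeric(Xte %*% beta))
  full_r2 - shuf_r2
}

# Day-balanced train/test split: per day, round(test_frac * n_day) test
# events (at least 1) when the day has >= 2 events; days with < 2 events go
# entirely to training with a warning.
stratified_split <- function(days, test_frac = 0.1) {
  test_idx <- integer(0)
  for (d in unique(days)) {
    idx <- which(days == d)
    if (length(idx) < 2) {
      warning("day ", d, " has fewer than 2 events; kept in training")
      next
    }
    k <- max(1, round(test_frac * length(idx)))
    test_idx <- c(test_idx, sample(idx, k))
  }
  list(train = setdiff(seq_along(days), test_idx), test = sort(test_idx))
}

#' Repeated day-balanced splits with forward selection and Huber fits
#'
#' For each of `n_splits` random splits (90/10 within each recording day),
#' standardizes on training rows, forward-selects feature blocks, fits the
#' Huber model, evaluates the full-model R^2 on the withheld rows, and
#' computes shuffle delta-R^2 for every retained feature (features not
#' retained in a split contribute 0 for that split). Coefficients, R^2 and
#' delta-R^2 are averaged over all splits; retention frequencies are
#' recorded.
#'
#' @param band_powers data.frame with event_id, channel, LFB, HFB (from
#'   [band_power_table()]).
#' @param ft feature table aligned by event_id.
#' @param n_splits number of random splits.
#' @param test_frac withheld fraction per day.
#' @param seed master RNG seed; all split and shuffle randomness derives
#'   from it.
#' @param delta Huber threshold.
#' @param bands bands to fit.
#' @return object of class `regression_result`: `full_r2` (electrode x band
#'   data.frame), `coefficients`, `delta_r2` and `retention` (long
#'   data.frames keyed by electrode, band and feature/column), `n_splits`,
#'   and per-split standardization checksums in `standardization`.
#' @export
run_splits <- function(band_powers, ft, n_splits = 200, test_frac = 0.1,
                       seed = 1, delta = 1.345, bands = c("LFB", "HFB")) {
  if (nrow(ft) < 20) stop("need at least 20 events")
  ft <- ft[match(sort(unique(band_powers$event_id)), ft$event_id), ]
  stopifnot(!anyNA(ft$event_id))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  channels <- sort(unique(band_powers$channel))
  yb <- list()
  for (b in bands) for (ch in channels) {
    d <- band_powers[band_powers$channel == ch, ]
    d <- d[match(ft$event_id, d$event_id), ]
    yb[[paste(ch, b)]] <- d[[b]]
  }
  feat_names <- c(continuous_features, categorical_features)
  acc <- list()       # per electrode-band accumulators
  std_sums <- numeric(n_splits)
  for (split in seq_len(n_splits)) {
    sp <- stratified_split(ft$day, test_frac)
    design <- build_design(ft, sp$train)
    std_sums[split] <- sum(design$center) + sum(design$scale)
    perm <- sample(length(sp$train))
    for (key in names(yb)) {
      y <- yb[[key]]
      retained <- forward_select(design, y[sp$train], rows = sp$train)
      if (length(retained) > 0) {
        cols <- c(1L, unlist(design$blocks[retained], use.names = FALSE))
        beta <- huber_fit(design$X[sp$train, cols, drop = FALSE],
                          y[sp$train], delta = delta)
        yhat <- as.numeric(design$X[sp$test, cols, drop = FALSE] %*% beta)
      } else {
        cols <- 1L
        beta <- stats::setNames(mean(y[sp$train]), "(Intercept)")
        yhat <- rep(beta, length(sp$test))
      }
      fr2 <- r2_score(y[sp$test], yhat)
      dr2 <- stats::setNames(numeric(length(feat_names)), feat_names)
      for (f in retained) {
        dr2[f] <- delta_r2(design, y, sp$train, sp$test, retained, f,
                           fr2, perm, delta = delta)
      }
      coef_full <- stats::setNames(numeric(ncol(design$X)),
                                   colnames(design$X))
      coef_full[names(beta)] <- beta
      a <- acc[[key]]
      if (is.null(a)) a <- list(r2 = 0, coef = 0, dr2 = 0,
                                ret = stats::setNames(numeric(length(feat_names)),
                                                      feat_names))
      a$r2 <- a$r2 + fr2
      a$coef <- a$coef + coef_full
      a$dr2 <- a$dr2 + dr2
      a$ret[retained] <- a$ret[retained] + 1
      acc[[key]] <- a
    }
  }
  full_r2 <- data.frame()
  coefs <- data.frame()
  drs <- data.frame()
  rets <- data.frame()
  for (key in names(acc)) {
    parts <- strsplit(key, " ")[[1]]
    ch <- as.integer(parts[1]); b <- parts[2]
    a <- acc[[key]]
    full_r2 <- rbind(full_r2, data.frame(channel = ch, band = b,
                                         full_r2 = a$r2 / n_splits))
    coefs <- rbind(coefs, data.frame(channel = ch, band = b,
                                     term = names(a$coef),
                                     coef = as.numeric(a$coef) / n_splits))
    drs <- rbind(drs, data.frame(channel = ch, band = b,
                                 feature = names(a$dr2),
                                 delta_r2 = as.numeric(a$dr2) / n_splits))
    rets <- rbind(rets, data.frame(channel = ch, band = b,
                                   feature = names(a$ret),
                                   retention = as.numeric(a$ret) / n_splits))
  }
  structure(list(full_r2 = full_r2, coefficients = coefs, delta_r2 = drs,
                 retention = rets, n_splits = n_splits,
                 standardization = std_sums),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result: %d electrode-band models, %d splits>\n",
              nrow(x$full_r2), x$n_splits))
  print(x$full_r2)
  invisible(x)
}
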