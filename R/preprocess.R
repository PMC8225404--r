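# Cleaning of multichannel neural recordings. Pipeline order is fixed:
# DC removal -> artifact zeroing -> band-pass/notch filtering + resampling to
# 500 Hz -> common-median rereferencing per electrode group -> bad-channel
# flagging. "IQR > k" rules are interpreted one-sided high: a value is
# abnormal when it exceeds median + k * IQR of that statistic.

# Lower-median convention for even-size groups, fixed for reproducibility.
median_low <- function(x) {
  s <- sort(x)
  s[ceiling(length(s) / 2)]
}

#' Remove DC drift by median subtraction
#'
#' Subtracts each channel's median voltage; idempotent.
#' @param rec a [neural_recording()].
#' @return the recording with per-channel median 0.
#' @export
remove_dc <- function(rec) {
  stopifnot(inherits(rec, "neural_recording"), ncol(rec$voltages) >= 1)
  med <- apply(rec$voltages, 1, stats::median)
  rec$voltages <- rec$voltages - med
  rec
}

#' Zero out widespread high-amplitude artifacts
#'
#' Computes the channel-averaged absolute voltage at each sample; samples
#' where it exceeds median + k * IQR (across samples) are zeroed on all
#' channels together with everything within `pad` seconds, and recorded in
#' the zeroed-sample mask.
#'
#' @param rec a DC-removed [neural_recording()].
#' @param k IQR multiplier (default 50).
#' @param pad zero-padding around each flagged sample, in seconds.
#' @return the recording with artifacts zeroed and `zeroed_mask` updated.
#' @export
zero_artifacts <- function(rec, k = 50, pad = 2) {
  stopifnot(inherits(rec, "neural_recording"))
  avg_abs <- colMeans(abs(rec$voltages))
  thr <- stats::median(avg_abs) + k * stats::IQR(avg_abs)
  bad <- which(avg_abs > thr)
  if (length(bad) > 0) {
    pad_n <- round(pad * rec$sample_rate)
    mask <- rep(FALSE, ncol(rec$voltages))
    for (b in bad) {
      lo <- max(1, b - pad_n)
      hi <- min(ncol(rec$voltages), b + pad_n)
      mask[lo:hi] <- TRUE
    }
    if (all(mask)) stop("recording unusable: all samples flagged as artifact")
    rec$voltages[, mask] <- 0
    rec$zeroed_mask <- rec$zeroed_mask | mask
  }
  rec
}

#' Band-pass, notch filter and resample to 500 Hz
#'
#' Zero-phase FIR band-pass at 1-200 Hz, notches at 60, 120 and 180 Hz, then
#' integer-factor decimation to 500 Hz. The zeroed-sample mask is decimated
#' alongside the data.
#'
#' @param rec a [neural_recording()] sampled at >= 500 Hz; the ratio
#'   sample_rate / 500 must be an integer.
#' @param band pass band in Hz.
#' @param notch line frequencies to notch (Hz), each with a +-2 Hz stop band.
#' @param target_rate output rate (Hz).
#' @return filtered recording at `target_rate`.
#' @export
filter_resample <- function(rec, band = c(1, 200), notch = c(60, 120, 180),
                            target_rate = 500) {
  stopifnot(inherits(rec, "neural_recording"))
  fs <- rec$sample_rate
  if (fs < target_rate) stop("sample rate below ", target_rate, " Hz")
  q <- fs / target_rate
  if (abs(q - round(q)) > 1e-9)
    stop("sample rate must be an integer multiple of the target rate")
  q <- as.integer(round(q))
  ntaps_bp <- min(2 * floor(3.3 / (band[1] / fs) / 2) + 1,
                  2 * floor((ncol(rec$voltages) - 1) / 2) + 1)
  h_bp <- fir_bandpass(band[1] / fs, band[2] / fs, ntaps_bp)
  h_notch <- lapply(notch[notch < band[2]], function(f0)
    fir_bandstop((f0 - 2) / fs, (f0 + 2) / fs,
                 2 * floor(3.3 / (2 / fs) / 2) + 1))
  out <- matrix(0, nrow(rec$voltages),
                length(decimate_by(rec$voltages[1, ], q)))
  for (ch in seq_len(nrow(rec$voltages))) {
    x <- filter_zerophase(rec$voltages[ch, ], h_bp)
    for (h in h_notch) x <- filter_zerophase(x, h)
    out[ch, ] <- decimate_by(x, q)
  }
  rec$voltages <- out
  rec$zeroed_mask <- decimate_by(rec$zeroed_mask, q)
  rec$sample_rate <- target_rate
  rec
}

#' Rereference to the common median within each electrode group
#'
#' For every sample, subtracts the median voltage across the channels of each
#' grid/strip/depth group (lower-median convention for even group sizes).
#' Singleton groups are left unchanged with a warning.
#'
#' @param rec a [neural_recording()] with group labels.
#' @return the rereferenced recording.
#' @export
rereference_common_median <- function(rec) {
  stopifnot(inherits(rec, "neural_recording"))
  for (g in unique(rec$group)) {
    idx <- which(rec$group == g)
    if (length(idx) == 1) {
      warning("group '", g, "' has a single channel; left unreferenced")
      next
    }
    ref <- apply(rec$voltages[idx, , drop = FALSE], 2, median_low)
    rec$voltages[idx, ] <- sweep(rec$voltages[idx, , drop = FALSE], 2, ref)
  }
  rec
}

#' Flag channels with abnormal variance or kurtosis
#'
#' A channel is flagged when its standard deviation exceeds
#' median + k_sd * IQR or its kurtosis exceeds median + k_kurt * IQR, medians
#' and IQRs taken across channels. Flagged channels are excluded from all
#' downstream analysis.
#'
#' @param rec a filtered [neural_recording()] with >= 4 channels.
#' @param k_sd,k_kurt IQR multipliers (defaults 5 and 10).
#' @return the recording with `bad_channels` updated.
#' @export
flag_bad_channels <- function(rec, k_sd = 5, k_kurt = 10) {
  stopifnot(inherits(rec, "neural_recording"))
  if (nrow(rec$voltages) < 4)
    stop("need at least 4 channels for stable IQR statistics")
  sds <- apply(rec$voltages, 1, stats::sd)
  kurt <- apply(rec$voltages, 1, function(x) {
    m <- mean(x); s2 <- mean((x - m)^2)
    if (s2 < 1e-300) return(0)
    mean((x - m)^4) / s2^2
  })
  bad <- sds > stats::median(sds) + k_sd * stats::IQR(sds) |
         kurt > stats::median(kurt) + k_kurt * stats::IQR(kurt)
  rec$bad_channels <- rec$bad_channels | bad
  rec
}

#' Run the full preprocessing chain
#'
#' DC removal, artifact zeroing, filtering/resampling, common-median
#' rereferencing and bad-channel flagging, in that fixed order.
#'
#' @param rec a raw [neural_recording()].
#' @param ... passed to the individual stages.
#' @return preprocessed recording at 500 Hz.
#' @export
preprocess_recording <- function(rec, ...) {
  rec <- remove_dc(rec)
  rec <- zero_artifacts(rec)
  rec <- filter_resample(rec, ...)
  rec <- rereference_common_median(rec)
  if (nrow(rec$voltages) >= 4) rec <- flag_bad_channels(rec)
  rec
}
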