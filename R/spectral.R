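# Event-aligned segmentation, bad-segment rejection, Morlet time-frequency
# log power, baseline subtraction and band averaging.
#
# Defaults: 10 s segments centered on movement onset at 500 Hz; frequency
# grid 4-124 Hz in 2 Hz steps; n_cycles = f/2 with a floor of 3; power in
# dB = 10*log10; baseline window [-1.5, -1] s; LFB = 8-32 Hz,
# HFB = 76-100 Hz; band power averaged over the first 0.5 s after onset.

default_freq_grid <- function() seq(4, 124, by = 2)

#' Extract 10 s voltage segments centered on each event
#'
#' @param rec preprocessed [neural_recording()] (500 Hz).
#' @param events pruned event table with `onset_time` (s) and an event id
#'   column `event_id` (added if absent).
#' @param half_window half width of the window in seconds.
#' @return list of `event_segment` objects (channels x samples voltage,
#'   onset at center). Events whose window would cross a recording edge are
#'   dropped; their ids are in `attr(, "dropped")`.
#' @export
extract_segments <- function(rec, events, half_window = 5) {
  stopifnot(inherits(rec, "neural_recording"))
  if (is.null(events$event_id)) events$event_id <- seq_len(nrow(events))
  fs <- rec$sample_rate
  nsamp <- ncol(rec$voltages)
  half_n <- round(half_window * fs)
  out <- list()
  dropped <- integer(0)
  for (i in seq_len(nrow(events))) {
    center <- round(events$onset_time[i] * fs) + 1
    lo <- center - half_n
    hi <- center + half_n - 1
    if (lo < 1 || hi > nsamp) {
      dropped <- c(dropped, events$event_id[i])
      next
    }
    seg <- list(event_id = events$event_id[i],
                voltages = rec$voltages[, lo:hi, drop = FALSE],
                sample_rate = fs,
                onset_index = half_n + 1,
                zeroed = sum(rec$zeroed_mask[lo:hi]))
    class(seg) <- "event_segment"
    out[[length(out) + 1]] <- seg
  }
  attr(out, "dropped") <- dropped
  out
}

# Mean log spectral density (dB) and 115-125 Hz band power of one segment,
# averaged over non-bad channels. The mean log PSD is taken over the
# analysis passband (1-124 Hz) so the band-pass stopband of preprocessed
# data does not drag clean segments below the 0 dB missing-data threshold.
segment_psd_stats <- function(seg, bad = NULL, freq_range = c(1, 124)) {
  chans <- seq_len(nrow(seg$voltages))
  if (!is.null(bad)) chans <- chans[!bad[chans]]
  mean_db <- 0
  band_db <- 0
  for (ch in chans) {
    p <- welch_psd(seg$voltages[ch, ], seg$sample_rate)
    psel <- p$freq >= freq_range[1] & p$freq <= freq_range[2]
    mean_db <- mean_db + mean(10 * log10(p$psd[psel] + 1e-300))
    sel <- p$freq >= 115 & p$freq <= 125
    band_db <- band_db + 10 * log10(mean(p$psd[sel]) + 1e-300)
  }
  c(mean_db = mean_db / length(chans), band_db = band_db / length(chans))
}

#' Reject segments with missing data or high-frequency artifacts
#'
#' Discards a segment if its mean log spectral density is below 0 dB (a
#' proxy for zeroed/missing data) or its 115-125 Hz power exceeds the
#' across-segment mean by more than 3 standard deviations.
#'
#' @param segments list from [extract_segments()].
#' @param bad optional logical vector of bad channels to exclude from the
#'   statistics.
#' @return surviving segments, with `attr(, "rejected")` holding the event
#'   ids and reasons of discarded segments.
#' @export
reject_bad_segments <- function(segments, bad = NULL) {
  if (length(segments) < 2)
    stop("need at least 2 segments for the SD criterion")
  stats_mat <- t(vapply(segments, segment_psd_stats, c(0, 0), bad = bad))
  low <- stats_mat[, 1] < 0
  # line-noise statistics over segments that pass the missing-data test,
  # so a zeroed segment's collapsed PSD cannot inflate the spread
  ref <- stats_mat[!low, 2]
  mu <- mean(ref)
  sdv <- if (length(ref) >= 2) stats::sd(ref) else 0
  high <- if (sdv > 0) stats_mat[, 2] > mu + 3 * sdv else rep(FALSE, length(segments))
  high <- high & !low
  drop <- low | high
  if (all(drop)) stop("all segments rejected")
  rejected <- data.frame(
    event_id = vapply(segments[drop], function(s) s$event_id, 1),
    reason = ifelse(low[drop], "low_power", "line_noise"))
  out <- segments[!drop]
  attr(out, "rejected") <- rejected
  out
}

#' Morlet time-frequency log power for one segment
#'
#' Complex Morlet wavelet transform on the configured frequency grid; power
#' in dB (10*log10 of squared amplitude). The outer 1 s on each side of the
#' window is within one wavelet length of the edge and flagged unreliable.
#'
#' @param seg an `event_segment`.
#' @param channel channel index.
#' @param freqs frequency grid (Hz).
#' @param n_cycles wavelet cycles; NULL for max(3, f/2).
#' @param decim keep every `decim`-th time sample.
#' @param kernels optional precomputed [morlet_kernels()] for `freqs`.
#' @return a [spectrogram()] with `attr(, "edge_seconds") = 1`.
#' @export
morlet_power <- function(seg, channel = 1, freqs = default_freq_grid(),
                         n_cycles = NULL, decim = 10L, kernels = NULL) {
  stopifnot(inherits(seg, "event_segment"))
  fs <- seg$sample_rate
  if (is.null(kernels)) kernels <- morlet_kernels(freqs, fs, n_cycles)
  amp <- morlet_transform(seg$voltages[channel, ], kernels)
  keep <- seq(1, ncol(amp), by = decim)
  power <- 20 * log10(amp[, keep, drop = FALSE] + 1e-300)
  times <- (keep - seg$onset_index) / fs
  sp <- spectrogram(power, freqs, times)
  attr(sp, "edge_seconds") <- 1
  sp
}

#' Subtract the pre-movement baseline from a spectrogram
#'
#' Per frequency, subtracts the mean log power over the baseline window
#' (default 1.5 to 1 s before onset), so power is expressed in dB relative
#' to baseline.
#'
#' @param sp a [spectrogram()] not yet baseline-subtracted.
#' @param baseline window in seconds relative to onset.
#' @return baseline-subtracted [spectrogram()].
#' @export
baseline_subtract <- function(sp, baseline = c(-1.5, -1)) {
  stopifnot(inherits(sp, "spectrogram"))
  if (sp$baseline_subtracted) stop("spectrogram already baseline-subtracted")
  sel <- sp$times >= baseline[1] & sp$times <= baseline[2]
  if (!any(sel)) stop("baseline window outside time grid")
  base <- rowMeans(sp$power[, sel, drop = FALSE])
  sp$power <- sp$power - base
  sp$baseline_subtracted <- TRUE
  sp$baseline <- baseline
  sp
}

#' Average baseline-subtracted log power over a band and time window
#'
#' @param sp baseline-subtracted [spectrogram()].
#' @param band "LFB" (8-32 Hz) or "HFB" (76-100 Hz), or a numeric length-2
#'   frequency interval; band membership is a closed interval on bin centers.
#' @param window time window in seconds (default first 0.5 s after onset).
#' @return mean log power (dB relative to baseline).
#' @export
band_average <- function(sp, band, window = c(0, 0.5)) {
  stopifnot(inherits(sp, "spectrogram"))
  if (!sp$baseline_subtracted) stop("baseline-subtract before band averaging")
  lim <- if (is.character(band)) band_limits(band) else band
  fsel <- sp$freqs >= lim[1] & sp$freqs <= lim[2]
  if (!any(fsel)) stop("band outside the frequency grid")
  tsel <- sp$times >= window[1] & sp$times <= window[2]
  mean(sp$power[fsel, tsel, drop = FALSE])
}

#' Per-event LFB/HFB band powers for a set of segments
#'
#' Convenience wrapper running [morlet_power()], [baseline_subtract()] and
#' [band_average()] per segment and channel.
#'
#' @param segments list of `event_segment`s.
#' @param channels channel indices (default all non-bad).
#' @param bad optional logical bad-channel vector.
#' @param freqs,n_cycles,decim passed to [morlet_power()].
#' @return data.frame with columns event_id, channel, LFB, HFB.
#' @export
band_power_table <- function(segments, channels = NULL, bad = NULL,
                             freqs = default_freq_grid(), n_cycles = NULL,
                             decim = 10L) {
  if (length(segments) == 0)
    return(data.frame(event_id = integer(0), channel = integer(0),
                      LFB = numeric(0), HFB = numeric(0)))
  nch <- nrow(segments[[1]]$voltages)
  if (is.null(channels)) {
    channels <- seq_len(nch)
    if (!is.null(bad)) channels <- channels[!bad[channels]]
  }
  kernels <- morlet_kernels(freqs, segments[[1]]$sample_rate, n_cycles)
  rows <- list()
  for (seg in segments) {
    for (ch in channels) {
      sp <- morlet_power(seg, ch, freqs, n_cycles, decim, kernels = kernels)
      sp <- baseline_subtract(sp)
      rows[[length(rows) + 1]] <- data.frame(
        event_id = seg$event_id, channel = ch,
        LFB = band_average(sp, "LFB"), HFB = band_average(sp, "HFB"))
    }
  }
  do.call(rbind, rows)
}
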