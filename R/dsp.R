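# Signal-processing primitives: windowed-sinc FIR design, zero-phase FIR
# filtering via FFT convolution, integer decimation, pink noise, Welch power
# spectral density, and a complex Morlet wavelet transform.

#' Windowed-sinc low-pass FIR coefficients
#'
#' Type-I linear-phase low-pass filter designed by the window method with a
#' Hamming window (stopband attenuation about 53 dB).
#'
#' @param fc cutoff frequency, normalized to the sampling rate (0 < fc < 0.5).
#' @param ntaps odd number of taps.
#' @return numeric vector of filter coefficients summing to ~1 at DC.
#' @keywords internal
fir_lowpass <- function(fc, ntaps) {
  stopifnot(fc > 0, fc < 0.5, ntaps %% 2 == 1)
  m <- (ntaps - 1) / 2
  n <- seq(-m, m)
  h <- 2 * fc * sinc(2 * fc * n)
  w <- 0.54 + 0.46 * cos(pi * n / m)
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Band-pass FIR as difference of two low-pass designs
#' @keywords internal
fir_bandpass <- function(f1, f2, ntaps) {
  stopifnot(f1 < f2)
  fir_lowpass(f2, ntaps) - fir_lowpass(f1, ntaps)
}

#' Band-stop (notch) FIR by spectral inversion of a band-pass
#' @keywords internal
fir_bandstop <- function(f1, f2, ntaps) {
  h <- -fir_bandpass(f1, f2, ntaps)
  m <- (ntaps - 1) / 2
  h[m + 1] <- h[m + 1] + 1
  h
}

#' Zero-phase FIR filtering
#'
#' Convolves with a linear-phase FIR kernel and removes the group delay, with
#' reflection padding at both ends so boundary samples see no filter ramp.
#' FFT-based convolution keeps long kernels affordable.
#'
#' @param x numeric signal.
#' @param h odd-length symmetric FIR kernel.
#' @return filtered signal, same length as `x`.
#' @keywords internal
filter_zerophase <- function(x, h) {
  ntaps <- length(h)
  stopifnot(ntaps %% 2 == 1)
  m <- (ntaps - 1) / 2
  n <- length(x)
  pad <- min(m, n - 1)
  # odd (antisymmetric) reflection, as in scipy filtfilt, to avoid kinks
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- fft_conv(xp, h)                       # length(xp) + ntaps - 1
  # full conv index of xp[i] center: i + m; xp offset of x[1] is pad + 1
  y[(pad + m + 1):(pad + m + n)]
}

# Linear convolution via FFT, returns length(x) + length(h) - 1.
fft_conv <- function(x, h) {
  nout <- length(x) + length(h) - 1
  nfft <- stats::nextn(nout, 2)
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(nout)] / nfft
}

# Complex variant used by the Morlet transform (kernel may be complex).
fft_conv_complex <- function(x, Hfft, nh, nfft) {
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  y <- stats::fft(X * Hfft, inverse = TRUE) / nfft
  y[seq_len(length(x) + nh - 1)]
}

#' Integer-factor decimation (no additional anti-alias filter)
#'
#' Assumes the caller has already band-limited the signal below the target
#' Nyquist (the preprocessing pipeline band-passes at 200 Hz before dropping
#' to 500 Hz).
#' @keywords internal
decimate_by <- function(x, q) {
  stopifnot(q >= 1, q == round(q))
  x[seq(1, length(x), by = q)]
}

#' 1/f ("pink") noise
#'
#' White Gaussian noise shaped in the frequency domain by 1/sqrt(f), mimicking
#' the broadband spectrum of cortical field potentials.
#'
#' @param n number of samples.
#' @param rate sampling rate in Hz.
#' @param scale RMS-ish amplitude scale (microvolts).
#' @return numeric vector of length `n`.
#' @keywords internal
pink_noise <- function(n, rate, scale = 1) {
  nfft <- stats::nextn(n, 2)
  white <- stats::rnorm(nfft)
  X <- stats::fft(white)
  f <- c(1, seq_len(nfft - 1))            # avoid division by zero at DC
  f <- pmin(f, nfft - f + 1)              # fold to two-sided frequency index
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE)) / nfft
  x <- x[seq_len(n)]
  scale * x / stats::sd(x)
}

#' Welch mean log power spectral density
#'
#' Hann-windowed periodogram averaged over 50%-overlapping 1 s windows.
#'
#' @param x numeric signal.
#' @param rate sampling rate in Hz.
#' @param seglen window length in samples (default one second).
#' @return list with `freq` (Hz) and `psd` (power per Hz, linear units).
#' @keywords internal
welch_psd <- function(x, rate, seglen = rate) {
  seglen <- min(seglen, length(x))
  hop <- max(1, floor(seglen / 2))
  starts <- seq(1, length(x) - seglen + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seglen) / (seglen + 1))
  u <- sum(w^2)
  acc <- numeric(floor(seglen / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + seglen - 1)] * w
    P <- Mod(stats::fft(seg))^2 / (u * rate)
    acc <- acc + P[seq_along(acc)]
  }
  list(freq = (seq_along(acc) - 1) * rate / seglen, psd = acc / length(starts))
}

#' Morlet wavelet family
#'
#' One complex Morlet kernel per frequency. The number of cycles defaults to
#' f/2 with a floor of 3, trading temporal for spectral resolution as
#' frequency grows. Kernels are amplitude-normalized so that a pure cosine of
#' amplitude A at frequency f yields |w * x| = A at its own frequency.
#'
#' @param freqs frequencies in Hz.
#' @param rate sampling rate in Hz.
#' @param n_cycles cycles per wavelet; NULL for max(3, f/2).
#' @return list of complex kernels.
#' @keywords internal
morlet_kernels <- function(freqs, rate, n_cycles = NULL) {
  lapply(freqs, function(f) {
    nc <- if (is.null(n_cycles)) max(3, f / 2) else n_cycles
    sigma_t <- nc / (2 * pi * f)
    half <- ceiling(5 * sigma_t * rate)
    t <- seq(-half, half) / rate
    env <- exp(-t^2 / (2 * sigma_t^2))
    k <- env * exp(2i * pi * f * t)
    2 * k / sum(env)   # cosine of amplitude A -> modulus A
  })
}

#' Morlet time-frequency amplitude
#'
#' @param x numeric signal.
#' @param kernels output of [morlet_kernels()].
#' @return matrix (frequency x time) of amplitudes (same units as `x`).
#' @keywords internal
morlet_transform <- function(x, kernels) {
  n <- length(x)
  maxh <- max(vapply(kernels, length, 1L))
  nfft <- stats::nextn(n + maxh - 1, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  out <- matrix(0, nrow = length(kernels), ncol = n)
  for (i in seq_along(kernels)) {
    k <- kernels[[i]]
    nh <- length(k)
    H <- stats::fft(c(k, numeric(nfft - nh)))
    y <- stats::fft(X * H, inverse = TRUE) / nfft
    half <- (nh - 1) / 2
    out[i, ] <- Mod(y[(half + 1):(half + n)])
  }
  out
}
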