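# Filtering and analytic-signal primitives shared by the spectral, PAC,
# coherence and NSTE modules.

# Second-order IIR notch (constrained biquad): unit gain away from f0, zero at
# f0, -3 dB width f0/q.
design_notch <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Zero-phase band-pass filter
#'
#' Windowed-sinc FIR band-pass (Hamming) applied forward-backward via
#' [signal::filtfilt] so there is no group delay. The filter order is three
#' cycles of the low band edge (the usual EEG band-pass convention), floored
#' at `min_order` taps.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param lo,hi band edges in Hz. `lo = 0` gives a low-pass; `hi >= fs/2` a
#'   high-pass.
#' @param min_order minimum FIR order.
#' @return The filtered signal (same length).
#' @export
band_filter <- function(x, fs, lo, hi, min_order = 16L) {
  nyq <- fs / 2
  if (hi <= lo) stop_("band_filter: need lo < hi")
  if (lo >= nyq) stop_("band_filter: low edge %g Hz at/above Nyquist", lo)
  hi <- min(hi, nyq * 0.999)
  # order set by the sharper of the two constraints: the low band edge and
  # a transition width of ~a quarter of the bandwidth (a narrow band high in
  # the spectrum still needs a long filter, or strong neighbours leak through
  # the stopband and in-band structure is clipped by the transition skirts)
  f_ref <- if (lo > 0) min(max(lo, 1), (hi - lo) / 4) else hi
  ord <- max(min_order, ceiling(3 * fs / f_ref))
  # short records cannot carry the ideal order; degrade gracefully down to
  # min_order before giving up
  ord <- min(ord, (length(x) - 2L) %/% 3L)
  ord <- ord + ord %% 2L                      # even order -> symmetric, integer delay
  if (ord < min_order)
    stop_("band_filter: signal too short (%d samples) for a filter on [%g, %g) Hz",
          length(x), lo, hi)
  h <- if (lo <= 0) {
    signal::fir1(ord, hi / nyq, type = "low")
  } else if (hi >= nyq * 0.999) {
    signal::fir1(ord, lo / nyq, type = "high")
  } else {
    signal::fir1(ord, c(lo, hi) / nyq, type = "pass")
  }
  signal::filtfilt(as.numeric(h), 1, x)
}

# Analytic signal by the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# White Gaussian noise restricted to [lo, hi), scaled to unit variance.
# Synthesized spectrally (FFT masking of white noise): exactly band-limited
# and much cheaper than time-domain filtering at generator scale. Uses the
# caller's RNG stream.
bandlimited_noise <- function(n, fs, lo, hi) {
  x <- rnorm(n)
  X <- fft(x)
  f <- seq(0, fs, length.out = n + 1L)[1:n]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  X[f < lo | f >= hi] <- 0i
  y <- Re(fft(X, inverse = TRUE) / n)
  y / sd(y)
}

# 1/f^alpha-shaped background noise (power ~ 1/f^alpha for f >= 1 Hz, flat
# below), unit variance. Shaped in the frequency domain from white noise.
pink_noise <- function(n, fs, alpha = 1) {
  x <- rnorm(n)
  X <- fft(x)
  f <- seq(0, fs, length.out = n + 1L)[1:n]
  f[f > fs / 2] <- fs - f[f > fs / 2]          # two-sided frequency axis
  g <- 1 / pmax(f, 1)^(alpha / 2)
  g[1] <- 0                                    # drop DC
  y <- Re(fft(X * g, inverse = TRUE) / n)
  y / sd(y)
}
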