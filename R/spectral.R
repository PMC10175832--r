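# Short-time Fourier band power: spectrograms on 2-s epochs with 1-s hop,
# Hann-tapered one-sided power spectral density, band-integrated summaries
# and between-stage fold-change maps.

hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# One-sided PSD of one epoch, density scaling: sum(psd) * df recovers the
# taper-weighted signal variance (Welch convention, 1/(fs * sum(w^2))).
epoch_psd <- function(x, fs, w) {
  X <- fft(x * w)
  n <- length(x)
  nf <- n %/% 2 + 1L
  p <- (Mod(X[1:nf])^2) / (fs * sum(w^2))
  p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
  p
}

#' Short-time power spectrogram
#'
#' Discrete-Fourier-transform spectrogram with Hann-tapered epochs
#' (default 2 s) and overlapping hops (default 1 s overlap), one per channel.
#' Power is a one-sided spectral density in uV^2/Hz on a grid of spacing
#' `1/epoch_s` Hz, scaled so that the density summed over frequency times the
#' grid spacing matches the tapered-signal variance.
#'
#' @param rec a `recording` (or a numeric vector with `fs` given).
#' @param epoch_s epoch length in seconds (default 2).
#' @param overlap_s overlap between consecutive epochs in seconds (default 1).
#' @param fs sampling rate, only when `rec` is a bare numeric vector.
#' @param channels channels to include (default all).
#' @return An object of class `power_spectrogram`: list with `freqs` (Hz),
#'   `epoch_centers` (s), and `power`, a named list of epoch x frequency
#'   matrices per channel.
#' @export
spectrogram <- function(rec, epoch_s = 2, overlap_s = 1, fs = NULL,
                        channels = NULL) {
  if (is.numeric(rec) && !is.matrix(rec)) {
    if (is.null(fs)) stop_("fs required for a bare signal")
    rec <- recording(matrix(rec, nrow = 1), fs, "x")
  }
  stopifnot(inherits(rec, "recording"))
  if (overlap_s >= epoch_s) stop_("overlap must be shorter than the epoch")
  fs <- rec$fs
  nper <- round(epoch_s * fs)
  hop <- round((epoch_s - overlap_s) * fs)
  n <- ncol(rec$signals)
  if (n < nper) stop_("recording shorter than one epoch")
  starts <- seq(1L, n - nper + 1L, by = hop)
  w <- hann(nper)
  nf <- nper %/% 2 + 1L
  freqs <- (0:(nf - 1L)) / epoch_s
  channels <- channels %||% rec$labels
  power <- lapply(channels, function(ch) {
    x <- get_channel(rec, ch)
    out <- matrix(0, length(starts), nf)
    for (k in seq_along(starts))
      out[k, ] <- epoch_psd(x[starts[k]:(starts[k] + nper - 1L)], fs, w)
    out
  })
  names(power) <- channels
  structure(list(freqs = freqs, epoch_centers = (starts - 1L) / fs + epoch_s / 2,
                 power = power, fs = fs, epoch_s = epoch_s,
                 overlap_s = overlap_s),
            class = "power_spectrogram")
}

#' @export
print.power_spectrogram <- function(x, ...) {
  cat(sprintf("<power_spectrogram> %d channels, %d epochs (%gs, %gs overlap), %d freqs 0-%g Hz\n",
              length(x$power), length(x$epoch_centers), x$epoch_s,
              x$overlap_s, length(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Band power from a spectrogram
#'
#' Integrates the spectral density over the half-open band `[lo, hi)` per
#' epoch and aggregates over the epochs whose centers fall in `interval`.
#'
#' @param spec a `power_spectrogram`.
#' @param band a `band_spec`, band name, or `c(lo, hi)` in Hz.
#' @param interval time interval in seconds `c(from, to)`; default the whole
#'   spectrogram.
#' @param channel channel name; default the first channel.
#' @param aggregate `"mean"` (default) or `"median"` over epochs.
#' @return Band power in uV^2 (scalar).
#' @export
band_power <- function(spec, band, interval = NULL, channel = NULL,
                       aggregate = c("mean", "median")) {
  stopifnot(inherits(spec, "power_spectrogram"))
  aggregate <- match.arg(aggregate)
  band <- as_band(band)
  if (band$lo >= max(spec$freqs)) stop_("band above the spectrogram range")
  channel <- channel %||% names(spec$power)[1]
  p <- spec$power[[channel]]
  if (is.null(p)) stop_("channel '%s' not in spectrogram", channel)
  keep <- rep(TRUE, nrow(p))
  if (!is.null(interval)) {
    keep <- spec$epoch_centers >= interval[1] & spec$epoch_centers <= interval[2]
    if (!any(keep)) stop_("no epochs inside interval [%g, %g] s", interval[1], interval[2])
  }
  df <- spec$freqs[2] - spec$freqs[1]
  bins <- spec$freqs >= band$lo & spec$freqs < band$hi
  per_epoch <- rowSums(p[keep, bins, drop = FALSE]) * df
  if (aggregate == "mean") mean(per_epoch) else median(per_epoch)
}

#' Channel-by-stage band-power map
#'
#' Mean band power per channel and stage (one band), the numeric substrate of
#' topographic band-power panels. The stage-level aggregate over epochs is the
#' median by default (robust to brief transients); the mean is available.
#'
#' @param rec a `recording`.
#' @param stages a `stage_table`.
#' @param band a band specification.
#' @param channels channels to include; default the EEG channels excluding the
#'   midline (Fz, Cz, Pz), the usual 16-locus topographic convention.
#' @param aggregate `"median"` (default) or `"mean"` over epochs.
#' @param epoch_s,overlap_s spectrogram parameters.
#' @return An object of class `band_power_map`: channel x stage matrix (uV^2)
#'   with the band attached.
#' @export
band_power_map <- function(rec, stages, band, channels = NULL,
                           aggregate = c("median", "mean"),
                           epoch_s = 2, overlap_s = 1) {
  stopifnot(inherits(rec, "recording"), inherits(stages, "stage_table"))
  aggregate <- match.arg(aggregate)
  band <- as_band(band)
  channels <- channels %||%
    setdiff(rec$labels[eeg_channels(rec)], MIDLINE)
  vals <- matrix(NA_real_, length(channels), nrow(stages),
                 dimnames = list(channels, stages$label))
  for (s in seq_len(nrow(stages))) {
    sl <- slice_stage(rec, stages, stages$label[s])
    sp <- spectrogram(sl, epoch_s, overlap_s, channels = channels)
    for (ch in channels)
      vals[ch, s] <- band_power(sp, band, channel = ch,
                                aggregate = if (aggregate == "median") "median" else "mean")
  }
  structure(list(values = vals, band = band, aggregate = aggregate),
            class = "band_power_map")
}

#' @export
print.band_power_map <- function(x, ...) {
  cat(sprintf("<band_power_map> band %s [%g, %g) Hz, %s over epochs\n",
              x$band$name, x$band$lo, x$band$hi, x$aggregate))
  print(signif(x$values, 4))
  invisible(x)
}

#' Between-stage fold change of band power
#'
#' Per-channel ratio of band power between two stages (columns of one or two
#' `band_power_map`s). Denominators below `eps` are floored at `eps` and
#' flagged in the `"floored"` attribute.
#'
#' @param num a `band_power_map` (numerator stage) or numeric vector.
#' @param den a `band_power_map` (denominator stage) or numeric vector.
#' @param stage_num,stage_den stage columns when maps are given.
#' @param eps denominator floor in uV^2; `NULL` (default) makes an exactly
#'   zero denominator an error.
#' @return Named vector of fold changes, with attribute `floored` naming the
#'   channels whose denominator was floored.
#' @export
fold_change <- function(num, den = NULL, stage_num = NULL, stage_den = NULL,
                        eps = NULL) {
  if (inherits(num, "band_power_map")) {
    if (is.null(den)) den <- num
    if (!identical(num$band[c("lo", "hi")], den$band[c("lo", "hi")]))
      stop_("fold_change: maps have different bands")
    a <- num$values[, stage_num %||% colnames(num$values)[2]]
    b <- den$values[, stage_den %||% colnames(den$values)[1]]
  } else {
    a <- num; b <- den
  }
  if (!identical(names(a), names(b)))
    stop_("fold_change: channel sets differ")
  floored <- character(0)
  if (any(b <= 0)) {
    if (is.null(eps)) stop_("zero denominator in fold_change (supply eps to floor)")
    floored <- names(b)[b < eps]
    b <- pmax(b, eps)
  } else if (!is.null(eps) && any(b < eps)) {
    floored <- names(b)[b < eps]
    b <- pmax(b, eps)
  }
  out <- a / b
  if (length(floored)) attr(out, "floored") <- floored
  out
}
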