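# Phase-amplitude coupling by the entropy-based modulation index:
# band-passed analytic phase and amplitude, phase-binned mean-amplitude
# distributions, comodulograms over (phase x amplitude) frequency grids,
# local and cross-regional electrode matrices, and circular-shift surrogate
# significance thresholds.

#' PAC analysis parameters
#'
#' @param n_bins number of phase bins over (-pi, pi] (default 18).
#' @param phase_bandwidth phase filter bandwidth in Hz; `NULL` (default) uses
#'   2 Hz below 20 Hz and 4 Hz above.
#' @param amp_bandwidth minimum amplitude filter bandwidth in Hz; the
#'   effective bandwidth is at least twice the phase frequency so the
#'   modulation side-bands pass.
#' @param window_s,hop_s stage-level analysis windows (seconds) and hop.
#' @param n_surrogates surrogate count for significance thresholds.
#' @param alpha significance level.
#' @return A list of class `pac_params`.
#' @export
pac_params <- function(n_bins = 18L, phase_bandwidth = NULL,
                       amp_bandwidth = NULL, window_s = 30, hop_s = 15,
                       n_surrogates = 200L, alpha = 0.05) {
  if (n_bins < 6L) stop_("need at least 6 phase bins")
  if (!(alpha > 0 && alpha < 1)) stop_("alpha must lie in (0,1)")
  structure(list(n_bins = as.integer(n_bins),
                 phase_bandwidth = phase_bandwidth,
                 amp_bandwidth = amp_bandwidth,
                 window_s = window_s, hop_s = hop_s,
                 n_surrogates = as.integer(n_surrogates), alpha = alpha),
            class = "pac_params")
}

phase_bw_at <- function(f, params)
  params$phase_bandwidth %||% (if (f < 20) 2 else 4)

#' Instantaneous phase of a band-passed signal
#'
#' Zero-phase band-pass followed by the analytic-signal angle.
#' One filter length at each edge is transient; stage-level callers discard it.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param band `c(lo, hi)` in Hz (or a `band_spec`).
#' @return Phase series in radians, (-pi, pi].
#' @export
extract_phase <- function(x, fs, band) {
  band <- as_band(band)
  if (band$hi - band$lo < 0.25)
    stop_("band [%g, %g) too narrow for filter design", band$lo, band$hi)
  Arg(analytic_signal(band_filter(x, fs, band$lo, band$hi)))
}

#' Instantaneous amplitude envelope of a band-passed signal
#'
#' @inheritParams extract_phase
#' @return Envelope series in the units of `x`.
#' @export
extract_amplitude <- function(x, fs, band) {
  band <- as_band(band)
  if (band$hi - band$lo < 0.25)
    stop_("band [%g, %g) too narrow for filter design", band$lo, band$hi)
  Mod(analytic_signal(band_filter(x, fs, band$lo, band$hi)))
}

phase_bin_index <- function(phase, n_bins) {
  # bins are half-open (lo, hi] over (-pi, pi]; phase == -pi folds into bin 1
  idx <- ceiling((phase + pi) / (2 * pi) * n_bins)
  pmin(pmax(idx, 1L), n_bins)
}

mi_from_bins <- function(bin_idx, amp, n_bins) {
  s <- rowsum(amp, bin_idx)
  cnt <- rowsum(rep(1, length(bin_idx)), bin_idx)
  P <- numeric(n_bins)
  P[as.integer(rownames(s))] <- s / cnt
  empty <- which(!(seq_len(n_bins) %in% as.integer(rownames(s))))
  tot <- sum(P)
  if (tot <= 0) stop_("all-zero amplitude: modulation index undefined")
  P <- P / tot
  H <- -sum(P[P > 0] * log(P[P > 0]))
  mi <- (log(n_bins) - H) / log(n_bins)
  if (length(empty)) {
    warning(sprintf("%d empty phase bin(s); their P set to 0", length(empty)),
            call. = FALSE)
    attr(mi, "empty_bins") <- empty
  }
  mi
}

#' Modulation index of phase-amplitude coupling
#'
#' Bins the phase series into `n_bins` equal bins over (-pi, pi], forms the
#' normalized mean-amplitude distribution P over bins, and returns
#' `MI = (log(n_bins) - H(P)) / log(n_bins)` (H: Shannon entropy). MI is 0
#' for a phase-independent envelope and 1 when the envelope is confined to a
#' single phase bin.
#'
#' @param phase phase series (radians).
#' @param amp amplitude envelope (non-negative), same length.
#' @param n_bins number of phase bins (default 18).
#' @return MI in \[0, 1\]. Empty phase bins trigger a warning and are
#'   reported in the `empty_bins` attribute.
#' @export
modulation_index <- function(phase, amp, n_bins = 18L) {
  if (length(phase) != length(amp)) stop_("phase and amp lengths differ")
  if (length(phase) < 10L * n_bins)
    warning("fewer than 10 samples per phase bin expected", call. = FALSE)
  mi_from_bins(phase_bin_index(phase, n_bins), amp, n_bins)
}

# Edge transient to discard (samples): one phase-filter length, capped at a
# fifth of the record so short windows remain usable.
edge_samples <- function(n, fs, lo) {
  min(floor(n / 5), ceiling(3 * fs / max(lo, 1)))
}

mi_pair <- function(x_phase, x_amp, fs, phase_band, amp_band, n_bins) {
  ph <- extract_phase(x_phase, fs, phase_band)
  am <- extract_amplitude(x_amp, fs, amp_band)
  e <- edge_samples(length(ph), fs, as_band(phase_band)$lo)
  keep <- (e + 1L):(length(ph) - e)
  modulation_index(ph[keep], am[keep], n_bins)
}

#' Phase-amplitude comodulogram
#'
#' MI over a grid of (phase frequency, amplitude frequency) cells. Cells where
#' the amplitude filter band reaches down to the phase band (amplitude low
#' edge <= phase high edge) cannot carry meaningful coupling and are masked
#' (`NA`), not zero. Phase frequencies conventionally span 1-50 Hz and
#' amplitude frequencies 2-256 Hz.
#'
#' @param x_phase signal providing the phase (numeric vector).
#' @param x_amp signal providing the amplitude; defaults to `x_phase`
#'   (local PAC).
#' @param fs sampling rate, Hz.
#' @param phase_freqs,amp_freqs centre-frequency grids in Hz (strictly
#'   increasing).
#' @param params a [pac_params()] object.
#' @return Object of class `comodulogram`: `phase_freqs`, `amp_freqs` and the
#'   `mi` matrix (phase x amplitude) with masked cells `NA`.
#' @export
comodulogram <- function(x_phase, x_amp = NULL, fs,
                         phase_freqs = seq(2, 48, by = 2),
                         amp_freqs = seq(8, 256, by = 8),
                         params = pac_params()) {
  x_amp <- x_amp %||% x_phase
  stopifnot(all(diff(phase_freqs) > 0), all(diff(amp_freqs) > 0))
  n <- length(x_phase)
  if (n / fs < 5 / min(phase_freqs))
    stop_("window shorter than 5 cycles of the lowest phase frequency")
  mi <- matrix(NA_real_, length(phase_freqs), length(amp_freqs),
               dimnames = list(phase_freqs, amp_freqs))
  for (i in seq_along(phase_freqs)) {
    fp <- phase_freqs[i]
    pbw <- phase_bw_at(fp, params)
    pband <- c(max(fp - pbw / 2, 0), fp + pbw / 2)
    ph <- extract_phase(x_phase, fs, pband)
    e <- edge_samples(n, fs, pband[1])
    keep <- (e + 1L):(n - e)
    bins <- phase_bin_index(ph[keep], params$n_bins)
    for (j in seq_along(amp_freqs)) {
      fa <- amp_freqs[j]
      # bandwidth 3x the phase frequency: the modulation side-bands sit at
      # +/- fp around the carrier and must pass at full gain (the fir1
      # transition skirts clip them in a 2*fp-wide band)
      abw <- max(params$amp_bandwidth %||% 0, 3 * fp, 2)
      aband <- c(fa - abw / 2, fa + abw / 2)
      if (aband[1] <= pband[2]) next                       # masked cell
      if (aband[1] >= fs / 2) next                         # above Nyquist
      am <- extract_amplitude(x_amp, fs, aband)
      mi[i, j] <- suppressWarnings(mi_from_bins(bins, am[keep], params$n_bins))
    }
  }
  structure(list(phase_freqs = phase_freqs, amp_freqs = amp_freqs, mi = mi,
                 params = params),
            class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  cat(sprintf("<comodulogram> %d x %d cells, MI range [%.4g, %.4g]\n",
              nrow(x$mi), ncol(x$mi), min(x$mi, na.rm = TRUE),
              max(x$mi, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.comodulogram <- function(x, ...) {
  graphics::image(x$phase_freqs, x$amp_freqs, x$mi,
                  xlab = "phase frequency (Hz)", ylab = "amplitude frequency (Hz)",
                  main = "comodulogram (MI)", ...)
  invisible(x)
}

# MI per window series, summarized by the median; windows of window_s with
# hop_s hop over one stage slice.
windowed_mi <- function(x_phase, x_amp, fs, phase_band, amp_band, params) {
  n <- length(x_phase)
  win <- round(params$window_s * fs)
  hop <- round(params$hop_s * fs)
  if (n <= win) {
    starts <- 1L; win <- n
  } else {
    starts <- seq(1L, n - win + 1L, by = hop)
  }
  vals <- vapply(starts, function(s) {
    idx <- s:(s + win - 1L)
    suppressWarnings(mi_pair(x_phase[idx], x_amp[idx], fs, phase_band,
                             amp_band, params$n_bins))
  }, 1)
  list(median = median(vals), series = vals,
       centers = (starts - 1L + win / 2) / fs)
}

#' Band-pair PAC electrode matrix
#'
#' MI for one (phase band, amplitude band) pair across electrodes. In
#' `"local"` mode phase and amplitude come from the same electrode (one value
#' per channel, the matrix diagonal). In `"cross"` mode (cross-regional PAC)
#' the phase is taken from prefrontal electrodes and the amplitude from
#' posterior electrodes, one value per (frontal, posterior) pair. The
#' amplitude band must be gamma1 or gamma2.
#'
#' PAC is computed in windows (`params$window_s`, hop `params$hop_s`) over the
#' stage and summarized by the median.
#'
#' @param rec a `recording`.
#' @param stages a `stage_table`; with `stage`, selects the analysis interval.
#'   Pass `NULL` to use the whole recording.
#' @param stage stage label.
#' @param phase_band,amp_band band specifications from the canonical set.
#' @param mode `"local"` or `"cross"`.
#' @param params a [pac_params()] object.
#' @param phase_channels,amp_channels channel sets; defaults: all EEG channels
#'   (local), or the frontal / posterior sets (cross).
#' @return Object of class `pac_matrix` with `values` (matrix), `mode`, bands.
#' @export
band_pac_matrix <- function(rec, stages = NULL, stage = NULL,
                            phase_band, amp_band,
                            mode = c("local", "cross"),
                            params = pac_params(),
                            phase_channels = NULL, amp_channels = NULL) {
  mode <- match.arg(mode)
  phase_band <- as_band(phase_band); amp_band <- as_band(amp_band)
  if (!amp_band$name %in% c("gamma1", "gamma2"))
    stop_("amplitude band must be gamma1 or gamma2 (got '%s')", amp_band$name)
  if (!is.null(stages)) rec <- slice_stage(rec, stages, stage)
  fs <- rec$fs
  if (mode == "local") {
    chans <- phase_channels %||% rec$labels[eeg_channels(rec)]
    vals <- vapply(chans, function(ch) {
      x <- get_channel(rec, ch)
      windowed_mi(x, x, fs, phase_band, amp_band, params)$median
    }, 1)
    values <- diag(vals, nrow = length(vals))
    dimnames(values) <- list(chans, chans)
  } else {
    pch <- phase_channels %||% intersect(FRONTAL_SET, rec$labels)
    ach <- amp_channels %||% intersect(POSTERIOR_SET, rec$labels)
    if (!all(pch %in% FRONTAL_SET))
      stop_("cross-regional phase channels must be prefrontal (%s)",
            paste(FRONTAL_SET, collapse = ", "))
    if (!all(ach %in% POSTERIOR_SET))
      stop_("cross-regional amplitude channels must be posterior (%s)",
            paste(POSTERIOR_SET, collapse = ", "))
    values <- matrix(NA_real_, length(pch), length(ach),
                     dimnames = list(pch, ach))
    for (p in pch) {
      xp <- get_channel(rec, p)
      for (a in ach) {
        xa <- get_channel(rec, a)
        values[p, a] <- windowed_mi(xp, xa, fs, phase_band, amp_band,
                                    params)$median
      }
    }
  }
  structure(list(values = values, mode = mode, phase_band = phase_band,
                 amp_band = amp_band),
            class = "pac_matrix")
}

#' @export
print.pac_matrix <- function(x, ...) {
  cat(sprintf("<pac_matrix> %s mode, phase %s x amplitude %s\n",
              x$mode, x$phase_band$name, x$amp_band$name))
  print(signif(x$values, 4))
  invisible(x)
}

#' Surrogate significance threshold for a modulation index
#'
#' Surrogates are circular time-shifts of the amplitude series by uniform
#' offsets of at least 1 s, which preserve both marginals while destroying the
#' phase-amplitude alignment. The threshold is the empirical (1 - alpha)
#' quantile of the surrogate MI distribution.
#'
#' @param phase phase series (radians).
#' @param amp amplitude envelope, same length.
#' @param fs sampling rate, Hz (sets the 1-s minimum shift).
#' @param params a [pac_params()] object (`n_surrogates >= 100`).
#' @return List with `observed` MI, `threshold`, `z` (surrogate z-score of the
#'   observed MI) and the `surrogates` vector.
#' @export
pac_surrogate_threshold <- function(phase, amp, fs, params = pac_params()) {
  if (params$n_surrogates < 100L) stop_("need at least 100 surrogates")
  n <- length(phase)
  if (n < 2.5 * fs) stop_("record too short for 1-s circular shifts")
  bins <- phase_bin_index(phase, params$n_bins)
  obs <- suppressWarnings(mi_from_bins(bins, amp, params$n_bins))
  max_shift <- n - round(fs)
  shifts <- round(runif(params$n_surrogates, round(fs), max_shift))
  sur <- vapply(shifts, function(s) {
    a <- c(amp[(s + 1L):n], amp[1:s])
    suppressWarnings(mi_from_bins(bins, a, params$n_bins))
  }, 1)
  thr <- as.numeric(quantile(sur, 1 - params$alpha, type = 1))
  list(observed = as.numeric(obs), threshold = thr,
       z = (as.numeric(obs) - mean(sur)) / sd(sur), surrogates = sur)
}
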