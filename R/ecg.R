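# ECG staging chain: adaptive-threshold R-peak detection, RR-interval /
# SDNN heart-rate-variability metrics, asystole detection as long inter-peak
# gaps, the electrocardiomatrix (beat-aligned image), and stage-table
# assembly from annotations plus an EEG-suppression criterion.

#' Detect ECG R peaks (variable-threshold method)
#'
#' The ECG is band-passed to 5-30 Hz (QRS energy), rectified, and peaks are
#' local maxima exceeding an adaptive threshold: half the rolling 2-s maximum,
#' floored at 3x the median absolute deviation of the rectified signal. A
#' 0.2-s refractory period suppresses double detections; each detection is
#' then refined to the local maximum of the raw signal (the R wave proper)
#' within +/-40 ms.
#'
#' @param ecg numeric ECG signal in microvolts.
#' @param fs sampling rate, Hz (> 60; the QRS complex is under-sampled below).
#' @return Object of class `rpeak_series`: `times` (s, strictly increasing)
#'   and `amplitudes` (uV). Flat or all-NA input yields an empty series.
#' @export
detect_r_peaks <- function(ecg, fs) {
  if (fs <= 60) stop_("fs = %g Hz under-samples the QRS complex", fs)
  if (length(ecg) < 2 * fs) stop_("need at least 2 s of ECG")
  empty <- structure(list(times = numeric(0), amplitudes = numeric(0)),
                     class = "rpeak_series")
  if (all(is.na(ecg))) return(empty)
  ecg[is.na(ecg)] <- 0
  if (max(ecg) - min(ecg) < 1e-9) return(empty)
  x <- abs(band_filter(ecg, fs, 5, 30))
  w <- round(2 * fs)
  thr <- pmax(0.5 * rolling_max(x, w), 3 * mad(x))
  n <- length(x)
  is_peak <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n],
               FALSE) & (x > thr)
  cand <- which(is_peak)
  if (!length(cand)) return(empty)
  # refractory: greedily keep the larger peak within 0.2 s
  refr <- round(0.2 * fs)
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refr) { keep <- c(keep, i); last <- i }
    else if (x[i] > x[keep[length(keep)]]) { keep[length(keep)] <- i; last <- i }
  }
  # refine to the raw R-wave maximum within +/-40 ms
  half <- round(0.04 * fs)
  ref <- vapply(keep, function(i) {
    lo <- max(1L, i - half); hi <- min(length(ecg), i + half)
    as.integer(lo + which.max(ecg[lo:hi]) - 1L)
  }, integer(1))
  ref <- sort(unique(ref))
  # a second refractory pass in case refinement merged neighbours
  if (length(ref) > 1L) {
    ok <- c(TRUE, diff(ref) >= refr)
    ref <- ref[ok]
  }
  structure(list(times = (ref - 1L) / fs, amplitudes = ecg[ref]),
            class = "rpeak_series")
}

#' @export
print.rpeak_series <- function(x, ...) {
  cat(sprintf("<rpeak_series> %d peaks", length(x$times)))
  if (length(x$times) > 1L)
    cat(sprintf(", mean HR %.1f bpm", 60 / mean(diff(x$times))))
  cat("\n")
  invisible(x)
}

#' Heart-rate-variability metrics from R peaks
#'
#' RR intervals are the successive R-peak differences in milliseconds; SDNN is
#' their population standard deviation (divisor n, not n-1; all detected beats
#' are used, with no ectopic/NN filtering by default).
#'
#' @param rpeaks an `rpeak_series` with at least 3 peaks.
#' @return List of class `hrv_metrics`: `rri` (ms), `mean_hr` (bpm,
#'   `60000 / mean(rri)`) and `sdnn` (ms).
#' @export
hrv_metrics <- function(rpeaks) {
  stopifnot(inherits(rpeaks, "rpeak_series"))
  if (length(rpeaks$times) < 3L) stop_("need at least 3 R peaks for HRV")
  rri <- diff(rpeaks$times) * 1000
  sdnn <- sqrt(mean((rri - mean(rri))^2))
  structure(list(rri = rri, mean_hr = 60000 / mean(rri), sdnn = sdnn),
            class = "hrv_metrics")
}

#' @export
print.hrv_metrics <- function(x, ...) {
  cat(sprintf("<hrv_metrics> %d RR intervals, mean HR %.1f bpm, SDNN %.1f ms\n",
              length(x$rri), x$mean_hr, x$sdnn))
  invisible(x)
}

#' Detect asystole events as long inter-peak gaps
#'
#' Every gap between consecutive R peaks of at least `min_gap_s` seconds is
#' reported as one event whose duration is the gap length.
#'
#' @param rpeaks an `rpeak_series`.
#' @param min_gap_s minimum gap in seconds (should exceed twice the typical
#'   RR interval).
#' @return data.frame with columns `start` (s, last beat before the gap) and
#'   `duration` (s); zero rows when no event (or no peaks).
#' @export
detect_asystole <- function(rpeaks, min_gap_s = 5) {
  stopifnot(inherits(rpeaks, "rpeak_series"))
  t <- rpeaks$times
  if (length(t) < 2L)
    return(data.frame(start = numeric(0), duration = numeric(0)))
  gaps <- diff(t)
  hit <- which(gaps >= min_gap_s)
  data.frame(start = t[hit], duration = gaps[hit])
}

#' Electrocardiomatrix (ECM)
#'
#' Stacks ECG epochs centered on successive R peaks into a beats x lag image,
#' rows sorted by R-peak time, exposing rhythm changes at a glance. Peaks
#' whose window would cross a record edge are dropped and counted.
#'
#' @param ecg numeric ECG signal (uV).
#' @param rpeaks an `rpeak_series` for this signal.
#' @param half_window half epoch width in seconds (default 1.5, wide enough
#'   to show P-QRS-T plus the neighbouring beats).
#' @param fs sampling rate, Hz.
#' @return Object of class `ecm_image`: `matrix` (beats x lag samples, each
#'   row spanning `2*half_window*fs + 1` samples), `beat_times`, `lags` (s),
#'   `half_window`, and `n_dropped` edge peaks.
#' @export
build_ecm <- function(ecg, rpeaks, half_window = 1.5, fs) {
  stopifnot(inherits(rpeaks, "rpeak_series"))
  hw <- round(half_window * fs)
  centers <- round(rpeaks$times * fs) + 1L
  ok <- centers - hw >= 1L & centers + hw <= length(ecg)
  if (!any(ok)) stop_("no R peak has a complete +/-%g s window", half_window)
  centers_ok <- centers[ok][order(rpeaks$times[ok])]
  m <- t(vapply(centers_ok, function(c0) ecg[(c0 - hw):(c0 + hw)],
                numeric(2L * hw + 1L)))
  structure(list(matrix = m, beat_times = sort(rpeaks$times[ok]),
                 lags = ((-hw):hw) / fs, half_window = half_window,
                 n_dropped = sum(!ok)),
            class = "ecm_image")
}

#' @export
print.ecm_image <- function(x, ...) {
  cat(sprintf("<ecm_image> %d beats x %d lag samples (+/-%g s), %d edge peak(s) dropped\n",
              nrow(x$matrix), ncol(x$matrix), x$half_window, x$n_dropped))
  invisible(x)
}

#' @export
plot.ecm_image <- function(x, ...) {
  graphics::image(x$lags, seq_len(nrow(x$matrix)), t(x$matrix),
                  xlab = "lag (s)", ylab = "beat (time order)",
                  main = "electrocardiomatrix", ...)
  invisible(x)
}

#' Assemble a stage table from config or annotations
#'
#' Explicit intervals pass through verbatim (validated). Otherwise a
#' ventilator-withdrawal annotation marks the start of S2; S2 ends at the
#' first time the 30-s moving RMS of the broadband EEG falls below
#' `suppression_frac` of the baseline (S1) RMS — the acute EEG suppression.
#' S1 is the pre-withdrawal period. Stages beyond S2 require explicit
#' intervals.
#'
#' @param rec a `recording` (needed for the detection path).
#' @param intervals optional explicit `stage_table` (or data.frame
#'   label/start/end) returned as-is after validation.
#' @param withdrawal_pattern regex locating the withdrawal annotation
#'   (case-insensitive).
#' @param suppression_frac RMS fraction defining suppression (default 0.25).
#' @param rms_window_s moving-RMS window (default 30 s).
#' @return A `stage_table`.
#' @export
build_stage_table <- function(rec, intervals = NULL,
                              withdrawal_pattern = "withdraw|ventilator",
                              suppression_frac = 0.25, rms_window_s = 30) {
  if (!is.null(intervals)) {
    if (inherits(intervals, "stage_table")) {
      # re-validate (callers may have edited the data.frame in place)
      return(stage_table(intervals$label, intervals$start, intervals$end))
    }
    return(stage_table(intervals$label, intervals$start, intervals$end))
  }
  stopifnot(inherits(rec, "recording"))
  ann <- rec$annotations
  hit <- grep(withdrawal_pattern, ann$text, ignore.case = TRUE)
  if (!length(hit))
    stop_("no explicit intervals and no annotation matching '%s'",
          withdrawal_pattern)
  t_w <- ann$time[hit[1]]
  if (t_w <= 0) stop_("withdrawal annotation at t = 0 leaves no baseline")
  idx <- eeg_channels(rec)
  broadband <- sqrt(colMeans(rec$signals[idx, , drop = FALSE]^2))
  mrms <- moving_rms(broadband, round(rms_window_s * rec$fs))
  i_w <- round(t_w * rec$fs)
  base_rms <- rms(broadband[1:i_w])
  below <- which(mrms < suppression_frac * base_rms)
  below <- below[below > i_w]
  t_end <- if (length(below)) (below[1] - 1L) / rec$fs else duration_s(rec)
  stage_table(c("S1", "S2"), c(0, t_w), c(t_w, t_end))
}
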