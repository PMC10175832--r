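#' Construct a multichannel recording
#'
#' Container for a polygraphic recording: EEG channels in microvolts plus, by
#' convention, one channel labelled `"ECG"`. Channels identified as ECG (label
#' `ECG`/`EKG`) are excluded from EEG-only operations such as average
#' re-referencing.
#'
#' @param signals numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param labels channel names, one per row of `signals`.
#' @param reference reference tag, `"as-recorded"` or `"average"`.
#' @param annotations data.frame with columns `time` (s) and `text`, or NULL.
#' @param start_time optional absolute start timestamp (POSIXct).
#' @return An object of class `recording`.
#' @export
recording <- function(signals, fs, labels,
                      reference = c("as-recorded", "average"),
                      annotations = NULL, start_time = NULL) {
  reference <- match.arg(reference)
  if (!is.matrix(signals)) signals <- matrix(signals, nrow = 1L)
  if (fs <= 0) stop_("sampling rate must be positive (got %g)", fs)
  if (length(labels) != nrow(signals))
    stop_("%d labels for %d channels", length(labels), nrow(signals))
  if (anyDuplicated(labels)) stop_("channel labels must be unique")
  rownames(signals) <- labels
  if (is.null(annotations))
    annotations <- data.frame(time = numeric(0), text = character(0))
  dur <- ncol(signals) / fs
  if (nrow(annotations) && any(annotations$time < 0 | annotations$time > dur))
    stop_("annotation times must lie within [0, %g] s", dur)
  structure(list(signals = signals, fs = fs, labels = labels,
                 reference = reference, annotations = annotations,
                 start_time = start_time),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
              nrow(x$signals), ncol(x$signals), x$fs,
              ncol(x$signals) / x$fs, x$reference))
  cat("  channels:", paste(x$labels, collapse = " "), "\n")
  if (nrow(x$annotations))
    cat(sprintf("  %d annotation(s)\n", nrow(x$annotations)))
  invisible(x)
}

#' @export
summary.recording <- function(object, ...) {
  s <- object$signals
  data.frame(channel = object$labels,
             rms_uV = apply(s, 1, rms),
             min_uV = apply(s, 1, min),
             max_uV = apply(s, 1, max),
             row.names = NULL)
}

duration_s <- function(rec) ncol(rec$signals) / rec$fs

#' Indices of EEG (non-ECG) channels
#' @param rec a `recording`.
#' @return integer indices into the channel rows.
#' @export
eeg_channels <- function(rec) which(!is_ecg_label(rec$labels))

get_channel <- function(rec, ch) {
  i <- match(normalize_channel(ch), rec$labels)
  if (is.na(i))
    stop_("channel '%s' not in recording (have: %s)", ch,
          paste(rec$labels, collapse = ", "))
  rec$signals[i, ]
}

#' Average re-reference the EEG channels
#'
#' Subtracts, at every sample, the mean over the EEG channels from each EEG
#' channel. The ECG channel is untouched. Re-referencing an already
#' average-referenced recording is an error rather than a silent no-op.
#'
#' @param rec a `recording` with `reference == "as-recorded"`.
#' @return The re-referenced `recording` (reference tag `"average"`).
#' @export
average_rereference <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (rec$reference == "average")
    stop_("recording is already average-referenced")
  idx <- eeg_channels(rec)
  if (length(idx) < 2L) stop_("need at least 2 EEG channels to re-reference")
  avg <- colMeans(rec$signals[idx, , drop = FALSE])
  rec$signals[idx, ] <- sweep(rec$signals[idx, , drop = FALSE], 2L, avg)
  rec$reference <- "average"
  rec
}

#' Zero-phase notch filtering of power-line interference
#'
#' Removes `base_hz` and its harmonics up to `base_hz * n_harmonics` with
#' second-order IIR notches (quality factor `q`) applied forward-backward
#' (zero phase, no group delay). Applied to EEG channels only unless
#' `include_ecg = TRUE`.
#'
#' @param rec a `recording`.
#' @param base_hz line frequency in Hz (default 60).
#' @param n_harmonics number of harmonics to remove, fundamental included.
#'   Defaults to all harmonics below Nyquist.
#' @param q notch quality factor (centre frequency / -3 dB width).
#' @param include_ecg also filter the ECG channel.
#' @return The filtered `recording`.
#' @export
notch_filter <- function(rec, base_hz = 60, n_harmonics = NULL, q = 30,
                         include_ecg = FALSE) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs / 2
  if (is.null(n_harmonics)) n_harmonics <- floor((nyq - 1e-9) / base_hz)
  if (n_harmonics < 1L) stop_("no harmonic of %g Hz below Nyquist (%g Hz)", base_hz, nyq)
  if (base_hz * n_harmonics >= nyq)
    stop_("harmonic %g Hz at or above Nyquist (%g Hz)", base_hz * n_harmonics, nyq)
  idx <- if (include_ecg) seq_len(nrow(rec$signals)) else eeg_channels(rec)
  for (k in seq_len(n_harmonics)) {
    ba <- design_notch(base_hz * k, rec$fs, q)
    for (i in idx)
      rec$signals[i, ] <- signal::filtfilt(ba$b, ba$a, rec$signals[i, ])
  }
  rec
}

#' Extract one labeled stage from a recording
#'
#' @param rec a `recording`.
#' @param stages a `stage_table`.
#' @param label stage label present in `stages`.
#' @return A `recording` restricted to samples in `[start, end)` of the stage;
#'   annotations inside the stage are re-timed to the slice origin.
#' @export
slice_stage <- function(rec, stages, label) {
  stopifnot(inherits(rec, "recording"), inherits(stages, "stage_table"))
  i <- match(label, stages$label)
  if (is.na(i))
    stop_("stage '%s' not in table (available: %s)", label,
          paste(stages$label, collapse = ", "))
  t0 <- stages$start[i]; t1 <- stages$end[i]
  if (t1 <= t0) stop_("stage '%s' is empty", label)
  if (t1 > duration_s(rec) + 1e-9)
    stop_("stage '%s' [%g, %g) extends past the recording (%.2f s)",
          label, t0, t1, duration_s(rec))
  i0 <- floor(t0 * rec$fs) + 1L
  i1 <- min(ncol(rec$signals), ceiling(t1 * rec$fs))
  ann <- rec$annotations
  keep <- ann$time >= t0 & ann$time < t1
  ann <- ann[keep, , drop = FALSE]
  ann$time <- ann$time - t0
  recording(rec$signals[, i0:i1, drop = FALSE], rec$fs, rec$labels,
            reference = rec$reference, annotations = ann,
            start_time = rec$start_time)
}

# --- stage tables ------------------------------------------------------------

#' Construct a stage table
#'
#' Ordered, non-overlapping labeled intervals (seconds) partitioning a
#' recording into clinically defined stages S1..Sn.
#'
#' @param label stage labels (unique).
#' @param start,end interval bounds in seconds; intervals must be strictly
#'   increasing and non-overlapping.
#' @return A data.frame of class `stage_table`.
#' @export
stage_table <- function(label, start, end) {
  stopifnot(length(label) == length(start), length(start) == length(end))
  if (anyDuplicated(label)) stop_("stage labels must be unique")
  if (any(end <= start)) stop_("every stage must have end > start")
  o <- order(start)
  label <- label[o]; start <- start[o]; end <- end[o]
  if (length(start) > 1L && any(start[-1] < end[-length(end)] - 1e-9))
    stop_("stage intervals overlap")
  structure(data.frame(label = label, start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("stage_table", "data.frame"))
}

#' Read a stage table from a 3-column CSV (label,start_s,end_s)
#' @param path CSV file path.
#' @return A `stage_table`.
#' @export
read_stage_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  cols <- c("label", "start_s", "end_s")
  if (!all(cols %in% names(df)))
    stop_("stage CSV must have columns label,start_s,end_s")
  stage_table(df$label, df$start_s, df$end_s)
}

#' Write a stage table as CSV
#' @param stages a `stage_table`.
#' @param path output CSV path.
#' @export
write_stage_table <- function(stages, path) {
  write.csv(data.frame(label = stages$label, start_s = stages$start,
                       end_s = stages$end),
            path, row.names = FALSE)
  invisible(path)
}
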