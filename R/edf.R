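# Minimal EDF / EDF+ I/O: 16-bit integer samples with per-signal physical
# scaling, fixed-length ASCII headers, optional "EDF Annotations" signal
# carrying time-stamped annotation lists (TALs). Covers what polygraphic
# EEG/ECG exports need; not a general-purpose EDF library.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop_("EDF header field too long: '%s' (> %d chars)", x, width)
  formatC(x, width = -width)
}

edf_num8 <- function(v) {
  for (digits in 6:1) {
    s <- formatC(v, digits = digits, format = "g", width = 1)
    if (nchar(s) <= 8L) return(edf_pad(s, 8L))
  }
  stop_("cannot format %g in 8 chars", v)
}

#' Write a recording to an EDF or EDF+ file
#'
#' Samples are quantized to 16-bit integers with per-channel physical scaling
#' (so the round-trip error is at most one quantization step). Annotations,
#' if present, are stored in an `EDF Annotations` signal (EDF+C).
#'
#' @param rec a `recording`.
#' @param path output file path.
#' @param record_s data-record duration in seconds (default 1).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_s = 1) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  spr <- fs * record_s
  if (abs(spr - round(spr)) > 1e-9)
    stop_("fs * record_s must be an integer number of samples")
  spr <- as.integer(round(spr))
  n <- ncol(rec$signals)
  n_rec <- ceiling(n / spr)
  has_ann <- nrow(rec$annotations) > 0L
  ns <- nrow(rec$signals) + as.integer(has_ann)

  # per-channel scaling
  pmin <- apply(rec$signals, 1, min); pmax <- apply(rec$signals, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  # annotation TALs per record
  ann_bytes_per_rec <- 0L
  tal_by_rec <- NULL
  if (has_ann) {
    tal_by_rec <- vector("list", n_rec)
    for (r in seq_len(n_rec)) {
      t0 <- (r - 1L) * record_s
      keep <- which(rec$annotations$time >= t0 &
                    rec$annotations$time < t0 + record_s)
      tal <- sprintf("+%g\x14\x14", t0)            # record timestamp TAL
      for (k in keep)
        tal <- paste0(tal, sprintf("+%g\x14%s\x14", rec$annotations$time[k],
                                   rec$annotations$text[k]))
      tal_by_rec[[r]] <- charToRaw(tal)
    }
    ann_bytes_per_rec <- max(vapply(tal_by_rec, length, 1L)) + 2L
    ann_bytes_per_rec <- ann_bytes_per_rec + ann_bytes_per_rec %% 2L  # int16 aligned
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)

  st <- rec$start_time %||% as.POSIXct("2000-01-01 00:00:00", tz = "UTC")
  header_bytes <- 256L * (1L + ns)
  wr(edf_pad("0", 8))
  wr(edf_pad("X X X X", 80))
  wr(edf_pad("Startdate X X X X", 80))
  wr(edf_pad(format(st, "%d.%m.%y"), 8))
  wr(edf_pad(format(st, "%H.%M.%S"), 8))
  wr(edf_pad(header_bytes, 8))
  wr(edf_pad(if (has_ann) "EDF+C" else "", 44))
  wr(edf_pad(n_rec, 8))
  wr(edf_pad(format(record_s), 8))
  wr(edf_pad(ns, 4))

  labels <- c(rec$labels, if (has_ann) "EDF Annotations")
  for (l in labels) wr(edf_pad(l, 16))
  for (l in labels) wr(edf_pad("", 80))                       # transducer
  for (l in labels) wr(edf_pad(if (l == "EDF Annotations") "" else "uV", 8))
  for (i in seq_len(ns)) wr(if (i <= nrow(rec$signals)) edf_num8(pmin[i]) else edf_num8(-1))
  for (i in seq_len(ns)) wr(if (i <= nrow(rec$signals)) edf_num8(pmax[i]) else edf_num8(1))
  for (i in seq_len(ns)) wr(edf_pad(dmin, 8))
  for (i in seq_len(ns)) wr(edf_pad(dmax, 8))
  for (l in labels) wr(edf_pad("", 80))                       # prefiltering
  for (i in seq_len(ns))
    wr(edf_pad(if (i <= nrow(rec$signals)) spr else ann_bytes_per_rec %/% 2L, 8))
  for (l in labels) wr(edf_pad("", 32))

  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    i0 <- (r - 1L) * spr + 1L
    i1 <- min(n, r * spr)
    for (i in seq_len(nrow(rec$signals))) {
      x <- rec$signals[i, i0:i1]
      if (length(x) < spr) x <- c(x, rep(0, spr - length(x)))
      dig <- as.integer(round((x - pmin[i]) / scale[i]) + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(dig, con, size = 2L, endian = "little")
    }
    if (has_ann) {
      tal <- tal_by_rec[[r]]
      pad <- raw(ann_bytes_per_rec - length(tal))
      writeBin(c(tal, pad), con)
    }
  }
  invisible(path)
}

#' Read an EDF or EDF+ file
#'
#' Low-level reader: returns every signal at its own sampling rate, header
#' metadata and any EDF+ annotations. Use [read_recording()] to obtain a
#' `recording` restricted to a montage.
#'
#' @param path EDF file path.
#' @return A list with `labels`, `fs` (per signal), `signals` (list of numeric
#'   vectors, physical units), `annotations` (data.frame time/text),
#'   `start_time`, `record_s`, `n_records`, and per-signal scaling info
#'   (`phys_min`, `phys_max`, `dig_min`, `dig_max`).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nbytes) rawToChar(readBin(con, "raw", nbytes))
  rdn <- function(nbytes) suppressWarnings(as.numeric(trimws(rd(nbytes))))

  version <- trimws(rd(8))
  if (version != "0") stop_("not an EDF file (version field '%s')", version)
  rd(80); rd(80)
  date <- trimws(rd(8)); time <- trimws(rd(8))
  header_bytes <- rdn(8)
  reserved <- trimws(rd(44))
  n_rec <- rdn(8)
  record_s <- rdn(8)
  ns <- as.integer(rdn(4))
  if (is.na(ns) || ns < 1L) stop_("unreadable EDF header (signal count)")

  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  units <- trimws(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_min <- vapply(seq_len(ns), function(i) rdn(8), 1)
  phys_max <- vapply(seq_len(ns), function(i) rdn(8), 1)
  dig_min <- vapply(seq_len(ns), function(i) rdn(8), 1)
  dig_max <- vapply(seq_len(ns), function(i) rdn(8), 1)
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rdn(8), 1))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (any(is.na(c(phys_min, phys_max, dig_min, dig_max, spr))))
    stop_("unreadable EDF header (signal scaling block)")

  is_ann <- labels == "EDF Annotations"
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  sigs <- lapply(seq_len(ns), function(i)
    if (is_ann[i]) raw(0) else numeric(n_rec * spr[i]))
  ann_raw <- raw(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        ann_raw <- c(ann_raw, readBin(con, "raw", 2L * spr[i]))
      } else {
        dig <- readBin(con, "integer", spr[i], size = 2L, signed = TRUE,
                       endian = "little")
        sigs[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
          (dig - dig_min[i]) * scale[i] + phys_min[i]
      }
    }
  }

  annotations <- parse_tals(ann_raw)
  start_time <- tryCatch(
    as.POSIXct(paste(date, time), format = "%d.%m.%y %H.%M.%S", tz = "UTC"),
    error = function(e) NULL)

  list(labels = labels[!is_ann], units = units[!is_ann],
       fs = spr[!is_ann] / record_s,
       signals = sigs[!is_ann],
       annotations = annotations,
       start_time = start_time, record_s = record_s, n_records = n_rec,
       phys_min = phys_min[!is_ann], phys_max = phys_max[!is_ann],
       dig_min = dig_min[!is_ann], dig_max = dig_max[!is_ann],
       edfplus = grepl("^EDF\\+", reserved))
}

# Parse EDF+ time-stamped annotation lists. Record-keeping TALs (empty text)
# are dropped.
parse_tals <- function(ann_raw) {
  out <- data.frame(time = numeric(0), text = character(0))
  if (!length(ann_raw)) return(out)
  txt <- rawToChar(ann_raw[ann_raw != as.raw(0)])
  tals <- strsplit(txt, "\x14\x14", fixed = TRUE)[[1]]
  # after splitting on the double-0x14 record stamps, each piece holds zero or
  # more "+onset(\x15dur)\x14text\x14" entries
  entries <- unlist(strsplit(txt, "\x14", fixed = TRUE))
  times <- numeric(0); texts <- character(0)
  i <- 1L
  while (i <= length(entries)) {
    e <- entries[i]
    if (grepl("^[+-][0-9.]+(\x15[0-9.]+)?$", e)) {
      onset <- as.numeric(sub("\x15.*$", "", e))
      if (i + 1L <= length(entries) &&
          !grepl("^[+-][0-9.]+(\x15[0-9.]+)?$", entries[i + 1L])) {
        times <- c(times, onset)
        texts <- c(texts, entries[i + 1L])
        i <- i + 2L
        next
      }
    }
    i <- i + 1L
  }
  keep <- nzchar(trimws(texts))
  data.frame(time = times[keep], text = texts[keep], stringsAsFactors = FALSE)
}

#' Read a recording from EDF restricted to a montage
#'
#' Channel labels are matched case-insensitively after normalization through
#' the alias table (T7->T3, T8->T4, P7->T5, P8->T6; ECG/EKG -> ECG). All
#' requested channels must share one sampling rate.
#'
#' @param path EDF/EDF+ file path.
#' @param montage channel labels to load; default: every recognized 10/20
#'   channel plus ECG present in the file.
#' @return A `recording` (reference tag `"as-recorded"`, annotations imported).
#' @export
read_recording <- function(path, montage = NULL) {
  edf <- read_edf(path)
  norm <- normalize_channel(edf$labels)
  if (is.null(montage)) {
    keep <- which(norm %in% c(CHANNELS_1020, "ECG"))
    if (!length(keep)) keep <- seq_along(norm)
  } else {
    want <- normalize_channel(montage)
    keep <- match(want, norm)
    if (anyNA(keep))
      stop_("channel(s) not found in EDF: %s (file has: %s)",
            paste(montage[is.na(keep)], collapse = ", "),
            paste(edf$labels, collapse = ", "))
  }
  fs <- unique(edf$fs[keep])
  if (length(fs) != 1L)
    stop_("requested channels have mixed sampling rates: %s",
          paste(unique(edf$fs[keep]), collapse = ", "))
  sig <- do.call(rbind, edf$signals[keep])
  recording(sig, fs, norm[keep], reference = "as-recorded",
            annotations = edf$annotations, start_time = edf$start_time)
}
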