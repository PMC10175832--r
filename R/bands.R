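#' Canonical EEG frequency bands
#'
#' Six half-open bands in Hz: delta \[0,4), theta \[4,8), alpha \[8,13),
#' beta \[13,25), gamma1 \[25,55) and gamma2 \[80,150). The 55--80 Hz gap is
#' deliberate: it brackets the 60 Hz power-line region so that notch-filter
#' residue never contaminates a band summary.
#'
#' @param name optional band name; if given, a single `band_spec` is returned.
#' @return A named list of `band_spec` objects, or one `band_spec`.
#' @export
#' @examples
#' eeg_bands()$gamma1
#' eeg_bands("alpha")
eeg_bands <- function(name = NULL) {
  tab <- list(
    delta  = band_spec("delta", 0, 4),
    theta  = band_spec("theta", 4, 8),
    alpha  = band_spec("alpha", 8, 13),
    beta   = band_spec("beta", 13, 25),
    gamma1 = band_spec("gamma1", 25, 55),
    gamma2 = band_spec("gamma2", 80, 150)
  )
  if (is.null(name)) return(tab)
  if (!name %in% names(tab))
    stop_("unknown band '%s'; available: %s", name, paste(names(tab), collapse = ", "))
  tab[[name]]
}

#' Construct a frequency-band specification
#'
#' @param name band label.
#' @param lo,hi band edges in Hz; the band is the half-open interval `[lo, hi)`.
#' @return An object of class `band_spec` with fields `name`, `lo`, `hi`.
#' @export
band_spec <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(lo < hi)) stop_("band '%s': need lo < hi (got [%g, %g))", name, lo, hi)
  structure(list(name = name, lo = lo, hi = hi), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s [%g, %g) Hz\n", x$name, x$lo, x$hi))
  invisible(x)
}

as_band <- function(band) {
  if (inherits(band, "band_spec")) return(band)
  if (is.character(band) && length(band) == 1L) return(eeg_bands(band))
  if (is.numeric(band) && length(band) == 2L) return(band_spec("custom", band[1], band[2]))
  stop_("cannot interpret band specification")
}

# --- 10/20 montage bookkeeping -----------------------------------------------

# The 19 scalp electrodes of the international 10/20 system (Fpz-referenced
# recordings carry these plus one ECG channel).
CHANNELS_1020 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                   "T3", "C3", "Cz", "C4", "T4",
                   "T5", "P3", "Pz", "P4", "T6", "O1", "O2")

MIDLINE <- c("Fz", "Cz", "Pz")

# Electrode groups used by the cross-regional PAC and long-range summaries.
FRONTAL_SET <- c("Fp1", "F7", "F3", "Fp2", "F4", "F8")
POSTERIOR_SET <- c("C3", "C4", "T3", "T4", "T5", "T6", "P3", "P4", "O1", "O2")

# Temporo-parieto-occipital ("posterior hot zone") electrode triplets.
TPO_LEFT <- c("O1", "P3", "T5")
TPO_RIGHT <- c("O2", "P4", "T6")

# Modern/legacy temporal-chain synonyms found in EDF exports.
CHANNEL_ALIASES <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

#' Normalize a channel label
#'
#' Case-insensitive match against the 10/20 set, applying the temporal-chain
#' alias table (T7->T3, T8->T4, P7->T5, P8->T6) and recognizing ECG/EKG labels.
#'
#' @param label character vector of raw labels.
#' @return normalized labels; unrecognized labels are returned trimmed but
#'   otherwise untouched.
#' @export
normalize_channel <- function(label) {
  lab <- trimws(label)
  out <- lab
  canon <- c(CHANNELS_1020, names(CHANNEL_ALIASES))
  for (i in seq_along(lab)) {
    if (grepl("e[ck]g", lab[i], ignore.case = TRUE)) { out[i] <- "ECG"; next }
    hit <- match(toupper(lab[i]), toupper(canon))
    if (!is.na(hit)) {
      nm <- canon[hit]
      out[i] <- if (nm %in% names(CHANNEL_ALIASES)) unname(CHANNEL_ALIASES[nm]) else nm
    }
  }
  out
}

is_ecg_label <- function(label) grepl("^e[ck]g$", label, ignore.case = TRUE)

#' Hemisphere of a 10/20 electrode
#'
#' 10/20 convention: odd terminal digit = left hemisphere, even = right,
#' trailing "z" = midline.
#'
#' @param ch channel label(s).
#' @return `"left"`, `"right"` or `"midline"` per channel.
#' @export
hemisphere <- function(ch) {
  vapply(ch, function(x) {
    if (grepl("z$", x, ignore.case = TRUE)) return("midline")
    d <- suppressWarnings(as.integer(sub(".*?(\\d+)$", "\\1", x)))
    if (is.na(d)) return("midline")
    if (d %% 2L == 1L) "left" else "right"
  }, character(1), USE.NAMES = FALSE)
}
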