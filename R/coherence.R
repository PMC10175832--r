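# Functional connectivity: Welch-averaged magnitude-squared coherence,
# per-band channel x channel matrices, temporo-parieto-occipital (TPO)
# summaries, long-range posterior-frontal pairs with ipsi/contra tagging,
# and classical t contrasts.

# Welch segment layout shared by msc_spectrum; returns start indices.
welch_segments <- function(n, nper, hop) {
  if (n < nper) stop_("signal shorter than one segment")
  seq(1L, n - nper + 1L, by = hop)
}

#' Magnitude-squared coherence spectrum (Welch)
#'
#' `MSC(f) = |Sxy|^2 / (Sxx Syy)` with cross- and auto-spectra averaged over
#' Hann-tapered overlapping segments. At least 8 segments are required: with a
#' single segment the estimate is identically 1 regardless of the signals.
#'
#' @param x,y numeric signals of equal length.
#' @param fs sampling rate, Hz.
#' @param seg_s segment length in seconds (default 2).
#' @param overlap_frac fractional overlap between segments (default 0.5).
#' @return List with `freqs` (Hz), `coherence` in \[0,1\] and `k` (segment
#'   count).
#' @export
msc_spectrum <- function(x, y, fs, seg_s = 2, overlap_frac = 0.5) {
  if (length(x) != length(y)) stop_("signals must have equal length")
  nper <- round(seg_s * fs)
  hop <- max(1L, round(nper * (1 - overlap_frac)))
  starts <- welch_segments(length(x), nper, hop)
  k <- length(starts)
  if (k < 8L)
    stop_("only %d Welch segments; need >= 8 (single-segment MSC is degenerate)", k)
  w <- hann(nper)
  nf <- nper %/% 2 + 1L
  sxx <- syy <- numeric(nf)
  sxy <- complex(nf)
  for (s in starts) {
    idx <- s:(s + nper - 1L)
    X <- fft(x[idx] * w)[1:nf]
    Y <- fft(y[idx] * w)[1:nf]
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  coh <- Mod(sxy)^2 / pmax(sxx * syy, .Machine$double.xmin)
  list(freqs = (0:(nf - 1L)) / seg_s, coherence = pmin(coh, 1), k = k)
}

#' Per-band coherence matrix
#'
#' Mean MSC over the in-band frequency bins for every channel pair within a
#' stage. Coherence analysis is restricted to oscillations below 150 Hz: a
#' band reaching above that cap is an error.
#'
#' @param rec a `recording`.
#' @param stages a `stage_table` (or `NULL` for the whole recording).
#' @param stage stage label.
#' @param band band specification (hi <= 150 Hz).
#' @param seg_s,overlap_frac Welch parameters (2-s Hann segments, 50% overlap).
#' @param channels channels to include; default all EEG channels.
#' @return Object of class `coherence_matrix`: symmetric channel x channel
#'   `values` in \[0,1\] with unit diagonal, plus `band` and `stage`.
#' @export
band_coherence <- function(rec, stages = NULL, stage = NULL, band,
                           seg_s = 2, overlap_frac = 0.5, channels = NULL) {
  band <- as_band(band)
  if (band$hi > 150 + 1e-9)
    stop_("coherence analysis is capped at 150 Hz (band '%s' reaches %g Hz)",
          band$name, band$hi)
  if (!is.null(stages)) rec <- slice_stage(rec, stages, stage)
  channels <- channels %||% rec$labels[eeg_channels(rec)]
  fs <- rec$fs
  nper <- round(seg_s * fs)
  hop <- max(1L, round(nper * (1 - overlap_frac)))
  starts <- welch_segments(ncol(rec$signals), nper, hop)
  if (length(starts) < 8L)
    stop_("stage too short: only %d Welch segments (need >= 8)", length(starts))
  w <- hann(nper)
  nf <- nper %/% 2 + 1L
  freqs <- (0:(nf - 1L)) / seg_s
  bins <- freqs >= band$lo & freqs < band$hi
  nc <- length(channels)
  # segment FFTs once per channel
  F <- array(0i, dim = c(nc, length(starts), nf))
  for (i in seq_len(nc)) {
    xi <- get_channel(rec, channels[i])
    for (s in seq_along(starts))
      F[i, s, ] <- fft(xi[starts[s]:(starts[s] + nper - 1L)] * w)[1:nf]
  }
  auto <- matrix(0, nc, nf)
  for (i in seq_len(nc)) auto[i, ] <- colSums(Mod(F[i, , ])^2)
  values <- diag(1, nc)
  dimnames(values) <- list(channels, channels)
  for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc) {
    sxy <- colSums(F[i, , ] * Conj(F[j, , ]))
    coh <- Mod(sxy)^2 / pmax(auto[i, ] * auto[j, ], .Machine$double.xmin)
    values[i, j] <- values[j, i] <- mean(pmin(coh[bins], 1))
  }
  structure(list(values = values, band = band, stage = stage,
                 k = length(starts)),
            class = "coherence_matrix")
}

#' @export
print.coherence_matrix <- function(x, ...) {
  cat(sprintf("<coherence_matrix> band %s, stage %s, %d segments\n",
              x$band$name, x$stage %||% "<all>", x$k))
  print(signif(x$values, 3))
  invisible(x)
}

tpo_pairs <- function(side) {
  ch <- if (side == "left") TPO_LEFT else TPO_RIGHT
  list(c(ch[1], ch[2]), c(ch[1], ch[3]), c(ch[2], ch[3]))
}

#' TPO-junction coherence summary
#'
#' Mean coherence within the three electrode pairs of one
#' temporo-parieto-occipital junction (left: O1P3, O1T5, P3T5; right: O2P4,
#' O2T6, P4T6).
#'
#' @param mat a `coherence_matrix` (or plain named square matrix).
#' @param side `"left"` or `"right"`.
#' @return List with `side`, per-`pairs` values and their arithmetic `mean`.
#' @export
tpo_summary <- function(mat, side = c("left", "right")) {
  side <- match.arg(side)
  v <- if (inherits(mat, "coherence_matrix")) mat$values else mat
  prs <- tpo_pairs(side)
  missing <- setdiff(unique(unlist(prs)), rownames(v))
  if (length(missing))
    stop_("channel(s) missing from matrix: %s", paste(missing, collapse = ", "))
  vals <- vapply(prs, function(p) v[p[1], p[2]], 1)
  names(vals) <- vapply(prs, function(p) paste0(p[1], p[2]), "")
  list(side = side, pairs = vals, mean = mean(vals))
}

#' Two-sided t contrast between two groups of connectivity values
#'
#' Classical Student t: pooled-variance unpaired, or paired on differences.
#' When both groups have zero variance and equal means the convention
#' `t = 0, p = 1` is returned rather than `NaN`.
#'
#' @param group_a,group_b numeric vectors (equal lengths when paired).
#' @param paired logical.
#' @return List with `t`, `df`, `p` (two-sided), group means and sizes.
#' @export
contrast_ttest <- function(group_a, group_b, paired = FALSE) {
  if (paired && length(group_a) != length(group_b))
    stop_("paired contrast needs equal lengths")
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_("each group needs at least 2 values")
  degenerate <- if (paired) var(group_a - group_b) == 0 else
    (var(group_a) == 0 && var(group_b) == 0)
  if (degenerate) {
    same <- if (paired) all(group_a == group_b) else
      mean(group_a) == mean(group_b)
    if (same)
      return(list(t = 0, df = if (paired) length(group_a) - 1L else
                    length(group_a) + length(group_b) - 2L,
                  p = 1, mean_a = mean(group_a), mean_b = mean(group_b),
                  n_a = length(group_a), n_b = length(group_b),
                  paired = paired))
  }
  tt <- t.test(group_a, group_b, paired = paired, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(group_a), mean_b = mean(group_b),
       n_a = length(group_a), n_b = length(group_b), paired = paired)
}

#' Long-range posterior-frontal coherence pairs
#'
#' Coherence between each electrode of one TPO junction and each prefrontal
#' electrode, tagged `contra` when the two channels lie in opposite
#' hemispheres (10/20 odd/even parity) and `ipsi` otherwise. Midline channels
#' are not admitted.
#'
#' @param mat a `coherence_matrix` covering the required channels.
#' @param tpo_side `"left"` or `"right"`.
#' @param frontal frontal channel set (default Fp1, F7, F3, Fp2, F4, F8).
#' @return data.frame with columns `posterior`, `frontal`, `coherence`,
#'   `laterality` (ipsi/contra).
#' @export
longrange_coherence <- function(mat, tpo_side = c("left", "right"),
                                frontal = FRONTAL_SET) {
  tpo_side <- match.arg(tpo_side)
  v <- if (inherits(mat, "coherence_matrix")) mat$values else mat
  post <- if (tpo_side == "left") TPO_LEFT else TPO_RIGHT
  if (any(hemisphere(c(post, frontal)) == "midline"))
    stop_("midline channels are excluded from hemispheric contrasts")
  missing <- setdiff(c(post, frontal), rownames(v))
  if (length(missing))
    stop_("channel(s) missing from matrix: %s", paste(missing, collapse = ", "))
  grid <- expand.grid(posterior = post, frontal = frontal,
                      stringsAsFactors = FALSE)
  grid$coherence <- mapply(function(p, f) v[p, f], grid$posterior, grid$frontal)
  grid$laterality <- ifelse(hemisphere(grid$posterior) == hemisphere(grid$frontal),
                            "ipsi", "contra")
  grid
}
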