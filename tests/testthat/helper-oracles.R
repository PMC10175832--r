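# Independent oracles used across the suite. These deliberately re-derive
# quantities with naive, transparent code paths (loops, direct histograms)
# so they stay independent of the package implementation.

# Modulation index by direct histogram computation.
mi_brute <- function(phase, amp, n_bins = 18L) {
  breaks <- seq(-pi, pi, length.out = n_bins + 1L)
  P <- numeric(n_bins)
  for (j in seq_len(n_bins)) {
    inb <- phase > breaks[j] & phase <= breaks[j + 1L]
    if (j == 1L) inb <- inb | phase <= breaks[1L]
    P[j] <- if (any(inb)) mean(amp[inb]) else 0
  }
  P <- P / sum(P)
  H <- -sum(ifelse(P > 0, P * log(P), 0))
  (log(n_bins) - H) / log(n_bins)
}

# Transfer entropy by explicit triple counting with nested loops.
te_brute <- function(src, tgt, delta, A) {
  n <- length(tgt)
  cnt <- array(0L, dim = c(A, A, A))
  for (t in seq_len(n - delta))
    cnt[tgt[t + delta], tgt[t], src[t]] <- cnt[tgt[t + delta], tgt[t], src[t]] + 1L
  N <- sum(cnt)
  te <- 0
  for (i in 1:A) for (j in 1:A) for (k in 1:A) {
    c3 <- cnt[i, j, k]
    if (c3 == 0) next
    n_jk <- sum(cnt[, j, k])
    n_ij <- sum(cnt[i, j, ])
    n_j <- sum(cnt[, j, ])
    te <- te + (c3 / N) * log2((c3 / n_jk) / (n_ij / n_j))
  }
  te
}

# Ordinal pattern of one window by sorting (independent of the package's
# pairwise-comparison coding).
rank_pattern <- function(w) order(order(w))

# Precision/recall of detected beat times against ground truth (+/- tol s).
beat_f1 <- function(detected, truth, tol = 0.01) {
  tp <- sum(vapply(truth, function(b) any(abs(detected - b) <= tol), TRUE))
  prec <- if (length(detected)) tp / length(detected) else 0
  rec <- if (length(truth)) tp / length(truth) else 0
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

# A small quiet recording for plumbing tests: named channels, optional ECG.
make_test_recording <- function(channels = c("C3", "C4", "O1", "ECG"),
                                fs = 256, dur = 10, sd = 10, seed = 99) {
  withr::with_seed(seed, {
    sig <- matrix(rnorm(length(channels) * fs * dur, sd = sd),
                  nrow = length(channels))
    recording(sig, fs, channels)
  })
}
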