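# Directed connectivity by normalized symbolic transfer entropy (NSTE):
# ordinal (rank-pattern) symbolization, plug-in transfer entropy over symbol
# triples, source-shuffle bias subtraction, and normalization by the target's
# conditional entropy. Asymmetric by construction: NSTE(x->y) != NSTE(y->x).

all_permutations <- function(d) {
  if (d == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(d - 1L))
    for (pos in seq_len(d))
      out[[length(out) + 1L]] <- append(p, d, after = pos - 1L)
  out
}

#' NSTE analysis parameters
#'
#' @param d embedding dimension (3, 4 or 5; alphabet size d!).
#' @param tau embedding delay in samples; `NULL` (default) sets one quarter
#'   cycle of the band centre frequency.
#' @param delta prediction horizon in samples; default equals `tau`.
#' @param n_shuffles source-shuffle count for the bias term (default 20).
#' @param window_s,hop_s stage-level analysis windows (seconds).
#' @param seed optional seed for the shuffle draws (makes a single call
#'   reproducible irrespective of the caller's RNG position).
#' @return A list of class `nste_params`.
#' @export
nste_params <- function(d = 3L, tau = NULL, delta = NULL, n_shuffles = 20L,
                        window_s = 30, hop_s = 15, seed = NULL) {
  if (!d %in% 3:5) stop_("embedding dimension d must be 3, 4 or 5")
  if (!is.null(tau) && tau < 1L) stop_("tau must be >= 1")
  if (!is.null(delta) && delta < 1L) stop_("delta must be >= 1")
  structure(list(d = as.integer(d), tau = tau, delta = delta,
                 n_shuffles = as.integer(n_shuffles),
                 window_s = window_s, hop_s = hop_s, seed = seed),
            class = "nste_params")
}

band_tau <- function(fs, band) {
  band <- as_band(band)
  fc <- (band$lo + band$hi) / 2
  max(1L, as.integer(round(fs / (4 * fc))))
}

#' Ordinal (rank-pattern) symbolization
#'
#' Maps each length-`d` delay vector `(x_t, x_(t+tau), ..., x_(t+(d-1)tau))`
#' to its rank permutation, one of the `d!` ordinal patterns. Ties are broken
#' by the earlier-index-smaller rule, so a constant signal yields one repeated
#' symbol (valid, flagged via the `constant` attribute).
#'
#' @param x numeric signal.
#' @param d embedding dimension.
#' @param tau embedding delay in samples.
#' @return Integer symbols in `1..d!`, length `length(x) - (d-1)*tau`, with
#'   attribute `alphabet = factorial(d)`.
#' @export
ordinal_symbolize <- function(x, d = 3L, tau = 1L) {
  n <- length(x)
  ne <- n - (d - 1L) * tau
  if (ne < 1L) stop_("signal shorter than the embedding span (d-1)*tau")
  m <- vapply(0:(d - 1L), function(j) x[(1L + j * tau):(ne + j * tau)],
              numeric(ne))
  if (ne == 1L) m <- matrix(m, nrow = 1L)
  r <- matrix(0L, ne, d)
  for (j in seq_len(d)) for (k in seq_len(d)) {
    if (k == j) next
    r[, j] <- r[, j] + (m[, k] < m[, j]) + ((m[, k] == m[, j]) & (k < j))
  }
  code <- as.vector(r %*% d^(0:(d - 1L)))
  perms <- all_permutations(d)
  perm_codes <- vapply(perms, function(p) sum((p - 1L) * d^(0:(d - 1L))), 1)
  sym <- match(code, perm_codes)
  attr(sym, "alphabet") <- factorial(d)
  if (length(unique(sym)) == 1L) attr(sym, "constant") <- TRUE
  sym
}

te_counts <- function(src_sym, tgt_sym, delta, A) {
  n <- length(tgt_sym)
  t_idx <- seq_len(n - delta)
  yf <- tgt_sym[t_idx + delta]; yp <- tgt_sym[t_idx]; xp <- src_sym[t_idx]
  code <- (yf - 1L) + A * (yp - 1L) + A * A * (xp - 1L) + 1L
  array(tabulate(code, A^3), dim = c(A, A, A))
}

te_from_counts <- function(cnt) {
  N <- sum(cnt)
  nz <- which(cnt > 0, arr.ind = TRUE)
  c_yfypxp <- cnt[nz]
  n_ypxp <- apply(cnt, c(2, 3), sum)
  n_yfyp <- apply(cnt, c(1, 2), sum)
  n_yp <- apply(cnt, 2, sum)
  sum(c_yfypxp / N *
        log2(c_yfypxp * n_yp[nz[, 2]] /
               (n_ypxp[nz[, c(2, 3), drop = FALSE]] *
                n_yfyp[nz[, c(1, 2), drop = FALSE]])))
}

#' Symbolic transfer entropy (plug-in, bits)
#'
#' `TE = sum p(yf, yp, xp) log2[ p(yf | yp, xp) / p(yf | yp) ]` with plug-in
#' joint frequencies over the symbol triples `(y_(t+delta), y_t, x_t)`.
#'
#' @param src_sym,tgt_sym integer symbol sequences of equal length (from
#'   [ordinal_symbolize()]).
#' @param delta prediction horizon in symbols.
#' @return TE in bits (>= 0 up to floating point). When fewer than
#'   `10 * alphabet^2` triples are available the result carries attribute
#'   `undersampled = TRUE`.
#' @export
symbolic_te <- function(src_sym, tgt_sym, delta = 1L) {
  if (length(src_sym) != length(tgt_sym)) stop_("symbol sequences differ in length")
  A <- max(attr(src_sym, "alphabet") %||% max(src_sym),
           attr(tgt_sym, "alphabet") %||% max(tgt_sym))
  cnt <- te_counts(src_sym, tgt_sym, as.integer(delta), as.integer(A))
  te <- te_from_counts(cnt)
  if (sum(cnt) < 10 * A^2) attr(te, "undersampled") <- TRUE
  te
}

# H(y_future | y_past) in bits, plug-in, from the same triple counts.
cond_entropy_future <- function(cnt) {
  n_yfyp <- apply(cnt, c(1, 2), sum)
  n_yp <- colSums(n_yfyp)
  N <- sum(n_yfyp)
  h_joint <- -sum((n_yfyp[n_yfyp > 0] / N) * log2(n_yfyp[n_yfyp > 0] / N))
  h_yp <- -sum((n_yp[n_yp > 0] / N) * log2(n_yp[n_yp > 0] / N))
  h_joint - h_yp
}

#' Normalized symbolic transfer entropy between two signals
#'
#' Both signals are band-passed, ordinal-symbolized, and the plug-in symbolic
#' transfer entropy source -> target is bias-corrected by the mean TE over
#' source-shuffled surrogates and normalized by the target's conditional
#' entropy `H(y_future | y_past)`:
#' `NSTE = max(0, (TE - mean shuffle TE) / H)`, clipped to \[0, 1\].
#'
#' @param src,tgt numeric signals (equal length).
#' @param fs sampling rate, Hz.
#' @param band band specification.
#' @param params an [nste_params()] object.
#' @return NSTE in \[0,1\], with attributes `te`, `bias` (mean shuffle TE) and
#'   `h` (conditional entropy, bits).
#' @export
nste <- function(src, tgt, fs, band, params = nste_params()) {
  if (length(src) != length(tgt)) stop_("signals must have equal length")
  if (max(tgt) - min(tgt) < 1e-12)
    stop_("target conditional entropy is zero (deterministic constant target)")
  band <- as_band(band)
  xs <- band_filter(src, fs, band$lo, band$hi)
  xt <- band_filter(tgt, fs, band$lo, band$hi)
  tau <- params$tau %||% band_tau(fs, band)
  delta <- params$delta %||% tau
  ss <- ordinal_symbolize(xs, params$d, tau)
  st <- ordinal_symbolize(xt, params$d, tau)
  nste_symbols(ss, st, delta, params)
}

nste_symbols <- function(ss, st, delta, params) {
  A <- attr(st, "alphabet") %||% max(st)
  cnt <- te_counts(ss, st, delta, as.integer(A))
  h <- cond_entropy_future(cnt)
  if (h <= 0)
    stop_("target conditional entropy is zero (deterministic constant target)")
  te <- te_from_counts(cnt)
  shuf <- with_seed(params$seed, {
    vapply(seq_len(params$n_shuffles), function(i) {
      te_from_counts(te_counts(sample(ss), st, delta, as.integer(A)))
    }, 1)
  })
  val <- min(1, max(0, (te - mean(shuf)) / h))
  attr(val, "te") <- te
  attr(val, "bias") <- mean(shuf)
  attr(val, "h") <- h
  val
}

#' Directed connectivity matrix (NSTE) for one band and stage
#'
#' NSTE for every ordered channel pair, computed in windows
#' (`params$window_s`, hop `params$hop_s`) and summarized by the median.
#' The diagonal (self-interaction) is undefined (`NA`).
#'
#' @param rec a `recording`.
#' @param stages a `stage_table` (or `NULL` for the whole recording).
#' @param stage stage label.
#' @param band band specification.
#' @param params an [nste_params()] object.
#' @param channels channels to include; default all EEG channels.
#' @return Object of class `nste_matrix`: source x target `values` in \[0,1\]
#'   with `NA` diagonal.
#' @export
directed_band_matrix <- function(rec, stages = NULL, stage = NULL, band,
                                 params = nste_params(), channels = NULL) {
  band <- as_band(band)
  if (!is.null(stages)) rec <- slice_stage(rec, stages, stage)
  channels <- channels %||% rec$labels[eeg_channels(rec)]
  fs <- rec$fs
  tau <- params$tau %||% band_tau(fs, band)
  delta <- params$delta %||% tau
  n <- ncol(rec$signals)
  win <- round(params$window_s * fs)
  hop <- round(params$hop_s * fs)
  if (n < 10 * fs) stop_("stage shorter than the 10-s minimum analysis window")
  starts <- if (n <= win) 1L else seq(1L, n - win + 1L, by = hop)
  win <- min(win, n)
  nc <- length(channels)
  acc <- array(NA_real_, dim = c(nc, nc, length(starts)),
               dimnames = list(channels, channels, NULL))
  filtered <- lapply(channels, function(ch)
    band_filter(get_channel(rec, ch), fs, band$lo, band$hi))
  for (s in seq_along(starts)) {
    idx <- starts[s]:(starts[s] + win - 1L)
    syms <- lapply(filtered, function(x)
      ordinal_symbolize(x[idx], params$d, tau))
    for (i in seq_len(nc)) for (j in seq_len(nc)) {
      if (i == j) next
      acc[i, j, s] <- as.numeric(nste_symbols(syms[[i]], syms[[j]], delta, params))
    }
  }
  values <- apply(acc, c(1, 2), median)
  structure(list(values = values, band = band, stage = stage,
                 tau = tau, delta = delta, n_windows = length(starts)),
            class = "nste_matrix")
}

#' @export
print.nste_matrix <- function(x, ...) {
  cat(sprintf("<nste_matrix> band %s, stage %s, tau=%d, %d window(s)\n",
              x$band$name, x$stage %||% "<all>", x$tau, x$n_windows))
  print(signif(x$values, 3))
  invisible(x)
}

#' Feedforward / feedback summary of a directed matrix
#'
#' FF = mean NSTE over (posterior TPO -> frontal) entries, FB = mean over
#' (frontal -> posterior TPO); each pair is tagged ipsi/contra by hemisphere
#' parity.
#'
#' @param mat an `nste_matrix` (or plain named square matrix, source rows,
#'   target columns).
#' @param tpo_side `"left"` or `"right"`.
#' @param frontal frontal channel set.
#' @return List with `ff`, `fb` (means) and `pairs`, a data.frame of per-pair
#'   values with `direction` (FF/FB) and `laterality` (ipsi/contra).
#' @export
ff_fb_summary <- function(mat, tpo_side = c("left", "right"),
                          frontal = FRONTAL_SET) {
  tpo_side <- match.arg(tpo_side)
  v <- if (inherits(mat, "nste_matrix")) mat$values else mat
  post <- if (tpo_side == "left") TPO_LEFT else TPO_RIGHT
  missing <- setdiff(c(post, frontal), rownames(v))
  if (length(missing))
    stop_("channel(s) missing from matrix: %s", paste(missing, collapse = ", "))
  grid <- rbind(
    data.frame(expand.grid(src = post, tgt = frontal,
                           stringsAsFactors = FALSE), direction = "FF"),
    data.frame(expand.grid(src = frontal, tgt = post,
                           stringsAsFactors = FALSE), direction = "FB"))
  grid$nste <- mapply(function(s, t) v[s, t], grid$src, grid$tgt)
  grid$laterality <- ifelse(hemisphere(grid$src) == hemisphere(grid$tgt),
                            "ipsi", "contra")
  list(ff = mean(grid$nste[grid$direction == "FF"]),
       fb = mean(grid$nste[grid$direction == "FB"]),
       pairs = grid)
}
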