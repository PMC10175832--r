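#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft sd median quantile t.test rnorm runif approx mad var setNames
#' @importFrom utils head tail read.csv write.csv packageVersion modifyList
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# All generator randomness flows through this so sessions are reproducible and
# no global state leaks between calls.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

rms <- function(x) sqrt(mean(x^2))

# Rolling maximum over a centred window of w samples (van Herk / Gil-Werman:
# block-wise prefix and suffix maxima, O(n) and vectorized).  Used by the
# adaptive R-peak threshold; zoo::rollmax is too slow at 512 Hz over minutes.
rolling_max <- function(x, w) {
  n <- length(x)
  if (w <= 1L) return(x)
  if (w >= n) return(rep(max(x), n))
  nblk <- ceiling(n / w)
  pad <- nblk * w - n
  xp <- c(x, rep(-Inf, pad))
  m <- matrix(xp, nrow = w)
  pre <- apply(m, 2, cummax)                       # prefix max within block
  suf <- apply(m[w:1, , drop = FALSE], 2, cummax)[w:1, , drop = FALSE]
  pre <- as.vector(pre); suf <- as.vector(suf)
  half <- (w - 1L) %/% 2L
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n + pad, lo + w - 1L)
  pmax(suf[lo], pre[hi])
}

# Moving RMS over a window of w samples (centred), via cumulative sums.
moving_rms <- function(x, w) {
  n <- length(x)
  w <- min(w, n)
  cs <- c(0, cumsum(x^2))
  half <- (w - 1L) %/% 2L
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, lo + w)
  lo <- pmin(lo, hi - 1L)
  sqrt((cs[hi + 1L] - cs[lo + 1L]) / (hi - lo))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
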