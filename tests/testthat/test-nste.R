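# Ordinal symbolization, symbolic transfer entropy, NSTE, directed matrices,
# FF/FB summaries.

test_that("ordinal symbolization matches rank patterns and length arithmetic", {
  # strictly increasing series: one repeated (identity) pattern
  s <- ordinal_symbolize(1:10, d = 3, tau = 1)
  expect_equal(length(unique(s)), 1L)
  expect_true(isTRUE(attr(s, "constant")))
  expect_equal(length(s), 10 - 2)

  # hand series: windows (3,1,2), (1,2,5), (2,5,4) -> distinct patterns that
  # agree with an order-based oracle
  x <- c(3, 1, 2, 5, 4)
  s2 <- ordinal_symbolize(x, d = 3, tau = 1)
  oracle <- vapply(1:3, function(t) paste(rank_pattern(x[t:(t + 2)]),
                                          collapse = ""), "")
  expect_equal(length(s2), 3)
  expect_equal(anyDuplicated(oracle[c(1, 2)]), 0)
  expect_equal(s2[1] == s2[2], oracle[1] == oracle[2])
  expect_equal(s2[2] == s2[3], oracle[2] == oracle[3])

  # random data: symbol equality structure identical to the oracle's
  withr::with_seed(1, y <- rnorm(200))
  sy <- ordinal_symbolize(y, d = 4, tau = 2)
  expect_equal(length(sy), 200 - 3 * 2)
  oy <- vapply(seq_along(sy), function(t)
    paste(rank_pattern(y[c(t, t + 2, t + 4, t + 6)]), collapse = ""), "")
  expect_equal(match(sy, unique(sy)), match(oy, unique(oy)))

  # ties broken earlier-index-smaller: constant pairs give one fixed pattern
  expect_equal(unique(ordinal_symbolize(rep(1, 10), 3, 1)),
               ordinal_symbolize(c(1, 2, 3), 3, 1)[1])
  expect_error(ordinal_symbolize(1:3, d = 3, tau = 2), "short")
})

test_that("symbolic TE equals a brute-force triple-histogram oracle", {
  withr::with_seed(2, {
    for (n in c(50, 100)) {
      src <- sample(6L, n, replace = TRUE)
      tgt <- sample(6L, n, replace = TRUE)
      attr(src, "alphabet") <- 6L; attr(tgt, "alphabet") <- 6L
      for (delta in c(1L, 3L)) {
        got <- suppressWarnings(symbolic_te(src, tgt, delta))
        expect_equal(as.numeric(got), te_brute(src, tgt, delta, 6L),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("TE recovers a deterministic copy and vanishes for independence", {
  withr::with_seed(3, {
    n <- 10000
    x <- sample(6L, n, replace = TRUE)
    y <- c(sample(6L, 1), x[1:(n - 1)])     # y_{t+1} = x_t
    attr(x, "alphabet") <- 6L; attr(y, "alphabet") <- 6L
    expect_equal(as.numeric(symbolic_te(x, y, 1L)), log2(6), tolerance = 0.05)
    y2 <- sample(6L, n, replace = TRUE); attr(y2, "alphabet") <- 6L
    expect_lte(as.numeric(symbolic_te(x, y2, 1L)), 0.05)
    short <- sample(6L, 80, replace = TRUE); attr(short, "alphabet") <- 6L
    expect_true(isTRUE(attr(suppressWarnings(symbolic_te(short, short, 1L)),
                            "undersampled")))
  })
})

test_that("NSTE detects direction, respects bounds, and is rank-invariant", {
  p <- nste_params(seed = 42)
  d <- gen_directed_pair(512, 20, "gamma1", lag = 0.006, gain = 1, seed = 4)
  fwd <- nste(d$x, d$y, 512, "gamma1", p)
  bwd <- nste(d$y, d$x, 512, "gamma1", p)
  expect_gt(as.numeric(fwd), as.numeric(bwd))
  expect_true(fwd >= 0 && fwd <= 1)

  # affine rescaling of either input leaves NSTE unchanged (ordinal symbols)
  expect_equal(as.numeric(nste(5 * d$x + 3, d$y, 512, "gamma1", p)),
               as.numeric(fwd), tolerance = 1e-12)

  # near-deterministic delayed copy: strong forward, weak backward transfer
  withr::with_seed(5, {
    x <- gen_directed_pair(512, 20, "gamma1", lag = 0.006, gain = 1)$x
    tau <- max(1L, round(512 / (4 * 40)))
    y <- c(rep(0, tau), x[1:(length(x) - tau)]) + rnorm(length(x), sd = 0.01)
    pc <- nste_params(tau = tau, delta = tau, seed = 6)
    expect_gte(as.numeric(nste(x, y, 512, "gamma1", pc)), 0.8)
    expect_lte(as.numeric(nste(y, x, 512, "gamma1", pc)), 0.1)
  })

  # swapping arguments with the same shuffle seed swaps the two directions
  expect_equal(as.numeric(nste(d$y, d$x, 512, "gamma1", p)),
               as.numeric(bwd), tolerance = 1e-12)
  expect_error(nste(d$x, rep(0, length(d$x)) + 1, 512, "gamma1", p))
})

test_that("directed matrix recovers an injected link with dominance", {
  spec <- session_spec(seed = 13)
  spec$stages <- list(spec$stages[[3]])    # directed-link stage, 60 s
  sess <- gen_session(spec)
  m <- directed_band_matrix(sess$recording, band = "gamma1",
                            params = nste_params(seed = 7),
                            channels = c("T5", "F4", "O2", "C3"))
  v <- m$values
  expect_true(all(is.na(diag(v))))
  ij <- which(v == max(v, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_equal(rownames(v)[ij[1]], "T5")
  expect_equal(colnames(v)[ij[2]], "F4")
  expect_gte(v["T5", "F4"], 2 * v["F4", "T5"])
})

test_that("FF/FB summary averages directed entries with laterality tags", {
  chans <- c("O1", "P3", "T5", "Fp1", "F7", "F3", "Fp2", "F4", "F8",
             "O2", "P4", "T6")
  v <- matrix(0.2, 12, 12, dimnames = list(chans, chans))
  s <- ff_fb_summary(v, "left")
  expect_equal(s$ff, s$fb)                 # symmetric matrix
  v["T5", "F3"] <- 0.8
  s2 <- ff_fb_summary(v, "left")
  expect_equal(s2$ff, mean(c(rep(0.2, 17), 0.8)))
  expect_equal(s2$fb, 0.2)
  tag <- s2$pairs
  expect_equal(tag$laterality[tag$src == "T5" & tag$tgt == "F4"], "contra")
  expect_equal(tag$laterality[tag$src == "F7" & tag$tgt == "P3"], "ipsi")
  expect_error(ff_fb_summary(v[1:5, 1:5], "left"), "missing")
})
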