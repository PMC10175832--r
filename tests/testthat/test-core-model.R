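# EDF I/O, montage handling, re-referencing, notch filtering, band table,
# stage slicing.

test_that("EDF round-trip preserves structure and quantizes within one step", {
  rec <- make_test_recording(c("C3", "ECG"), fs = 256, dur = 4, sd = 50)
  rec$annotations <- data.frame(time = c(1.25, 3.5),
                                text = c("ventilator withdrawal", "note"))
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  back <- read_recording(f)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$labels, rec$labels)
  expect_equal(ncol(back$signals), ncol(rec$signals))
  expect_equal(back$reference, "as-recorded")
  for (i in 1:2) {
    step <- (max(rec$signals[i, ]) - min(rec$signals[i, ])) / (32767 - (-32768))
    expect_lte(max(abs(back$signals[i, ] - rec$signals[i, ])), step)
  }
  expect_equal(back$annotations$time, c(1.25, 3.5))
  expect_equal(back$annotations$text, c("ventilator withdrawal", "note"))
})

test_that("reader normalizes channel aliases and names missing channels", {
  rec <- make_test_recording(c("T7", "P8", "EKG"), fs = 128, dur = 2)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  back <- read_recording(f)
  expect_setequal(back$labels, c("T3", "T6", "ECG"))
  expect_error(read_recording(f, montage = c("T3", "O2")), "O2")
  expect_error(read_edf(withr::local_tempfile(lines = "not an EDF header")),
               "EDF")
})

test_that("average re-reference zeroes the EEG mean and spares the ECG", {
  # three EEG channels valued (1, 2, 3) at every sample -> (-1, 0, 1)
  sig <- rbind(matrix(rep(1:3, each = 100), 3, byrow = TRUE),
               matrix(5, 1, 100))
  rec <- recording(sig, 100, c("C3", "C4", "O1", "ECG"))
  out <- average_rereference(rec)
  expect_equal(unname(out$signals[1:3, 1]), c(-1, 0, 1))
  expect_equal(unname(out$signals["ECG", ]), rep(5, 100))
  expect_equal(out$reference, "average")
  expect_error(average_rereference(out), "already")

  # identical EEG channels -> all-zero output
  same <- recording(matrix(rep(sin(1:200), 3), 3, byrow = TRUE), 100,
                    c("C3", "C4", "O1"))
  expect_lt(max(abs(average_rereference(same)$signals)), 1e-12)

  # random 19-channel montage: per-sample means vanish; idempotent in effect
  big <- make_test_recording(c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                               "T3", "C3", "Cz", "C4", "T4", "T5", "P3",
                               "Pz", "P4", "T6", "O1", "O2"),
                             fs = 100, dur = 10)
  ref <- average_rereference(big)
  expect_lt(max(abs(colMeans(ref$signals))), 1e-9)
  again <- sweep(ref$signals, 2L, colMeans(ref$signals))
  expect_lt(max(abs(again - ref$signals)), 1e-9)
})

test_that("notch filter removes line harmonics and spares the passband", {
  fs <- 512
  tt <- (0:(fs * 20 - 1)) / fs
  mid <- (fs * 2 + 1):(fs * 18)          # discard 2 s at each edge
  tone <- function(f) sin(2 * pi * f * tt)
  rms <- function(x) sqrt(mean(x^2))

  r60 <- recording(matrix(tone(60), 1), fs, "C3")
  out60 <- notch_filter(r60)
  atten_db <- 20 * log10(rms(r60$signals[1, mid]) / rms(out60$signals[1, mid]))
  expect_gte(atten_db, 40)

  r10 <- recording(matrix(tone(10), 1), fs, "C3")
  out10 <- notch_filter(r10)
  pass_db <- 20 * log10(rms(r10$signals[1, mid]) / rms(out10$signals[1, mid]))
  expect_lte(abs(pass_db), 0.5)

  rdc <- recording(matrix(rep(3, fs * 20), 1), fs, "C3")
  outdc <- notch_filter(rdc)
  # DC sits in the passband; only slow filtfilt initialization tails remain
  expect_lt(max(abs(outdc$signals[1, mid] - 3)) / 3, 1e-3)

  expect_error(notch_filter(r60, base_hz = 60, n_harmonics = 5), "Nyquist")
})

test_that("notch and re-reference commute on random input", {
  rec <- make_test_recording(c("C3", "C4", "O1", "O2"), fs = 256, dur = 6)
  a <- notch_filter(average_rereference(rec))
  b <- average_rereference(notch_filter(rec))
  expect_lt(max(abs(a$signals - b$signals)), 1e-6)
})

test_that("canonical band table partitions [0,55) and [80,150) without overlap", {
  b <- eeg_bands()
  expect_named(b, c("delta", "theta", "alpha", "beta", "gamma1", "gamma2"))
  edges <- t(vapply(b, function(x) c(x$lo, x$hi), numeric(2)))
  expect_equal(unname(edges[, 1]), c(0, 4, 8, 13, 25, 80))
  expect_equal(unname(edges[, 2]), c(4, 8, 13, 25, 55, 150))
  # contiguous up to 55, then the deliberate 55-80 gap
  expect_equal(unname(edges[2:5, 1]), unname(edges[1:4, 2]))
  expect_gt(edges["gamma2", 1], edges["gamma1", 2])
})

test_that("stage slicing partitions the recording and validates labels", {
  rec <- make_test_recording("C3", fs = 512, dur = 10)
  st <- stage_table(c("S1", "S2", "S3"), c(0, 2, 5), c(2, 5, 10))
  sl <- slice_stage(rec, st, "S2")
  expect_equal(ncol(sl$signals), 1536)    # (5-2) s at 512 Hz
  total <- sum(vapply(st$label, function(l)
    ncol(slice_stage(rec, st, l)$signals), 1))
  expect_equal(total, ncol(rec$signals))
  expect_error(slice_stage(rec, st, "S9"), "S1.*S2.*S3")
  expect_error(stage_table(c("A", "B"), c(0, 1), c(2, 3)), "overlap")
})

test_that("stage table CSV round-trips", {
  st <- stage_table(c("S1", "S2"), c(0, 60), c(60, 150))
  f <- withr::local_tempfile(fileext = ".csv")
  write_stage_table(st, f)
  back <- read_stage_table(f)
  expect_equal(back$label, st$label)
  expect_equal(back$start, st$start)
  expect_equal(back$end, st$end)
})
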