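# R-peak detection, HRV, asystole, the electrocardiomatrix, and stage-table
# assembly.

test_that("R-peak detection handles degenerate inputs and enforces contracts", {
  expect_length(detect_r_peaks(numeric(1024), 512)$times, 0)
  expect_length(detect_r_peaks(rep(NA_real_, 1024), 512)$times, 0)
  expect_error(detect_r_peaks(numeric(5000), 50), "under-sample")
  expect_error(detect_r_peaks(numeric(100), 512), "2 s")
})

test_that("clean synthetic ECG is detected with full precision and recall", {
  e <- gen_ecg(512, 60, list(type = "constant", rr_s = 1), seed = 21)
  rp <- detect_r_peaks(e$signal, 512)
  expect_equal(beat_f1(rp$times, e$beat_times, tol = 0.01), 1.0)
  h <- hrv_metrics(rp)
  expect_equal(h$mean_hr, 60, tolerance = 0.5 / 60)
  expect_lt(h$sdnn, 3)

  # heart-rate ramp: detected RRI trajectory tracks the generator within 2%
  r <- gen_ecg(512, 60, list(type = "ramp", hr_from = 60, hr_to = 30),
               seed = 22)
  rr <- detect_r_peaks(r$signal, 512)
  expect_equal(length(rr$times), length(r$beat_times))
  rel <- abs(diff(rr$times) - diff(r$beat_times)) / diff(r$beat_times)
  expect_lt(max(rel), 0.02)
})

test_that("R-peak detection is shift-equivariant", {
  e <- gen_ecg(512, 30, list(type = "constant", rr_s = 0.8), seed = 23)
  rp0 <- detect_r_peaks(e$signal, 512)
  shift <- 512 %/% 4
  delayed <- c(numeric(shift), e$signal[1:(length(e$signal) - shift)])
  rp1 <- detect_r_peaks(delayed, 512)
  common <- min(length(rp0$times), length(rp1$times))
  dt <- rp1$times[seq_len(common)] - rp0$times[seq_len(common)] - shift / 512
  expect_lte(max(abs(dt)), 1 / 512 + 1e-9)
})

test_that("HRV metrics use the population SD over all detected beats", {
  # alternating 900/1100 ms RR intervals -> SDNN exactly 100 ms
  times <- cumsum(c(0, rep(c(0.9, 1.1), 10)))
  rp <- structure(list(times = times, amplitudes = rep(1000, length(times))),
                  class = "rpeak_series")
  h <- hrv_metrics(rp)
  expect_equal(h$sdnn, 100)
  expect_equal(h$mean_hr, 60000 / mean(diff(times) * 1000))
  expect_error(hrv_metrics(structure(list(times = c(0, 1),
                                          amplitudes = c(1, 1)),
                                     class = "rpeak_series")),
               "3 R peaks")

  # generator SDNN recovered within 15% across a range of variabilities
  for (sdms in c(10, 50, 100)) {
    g <- gen_ecg(512, 240, list(type = "gaussian", mean_rr_s = 1,
                                sd_ms = sdms), seed = 400 + sdms)
    h <- hrv_metrics(detect_r_peaks(g$signal, 512))
    expect_lt(abs(h$sdnn - sdms) / sdms, 0.15)
  }
})

test_that("asystole detection reports inter-peak gaps above threshold", {
  clean <- gen_ecg(512, 60, list(type = "constant", rr_s = 1), seed = 24)
  rp <- detect_r_peaks(clean$signal, 512)
  expect_equal(nrow(detect_asystole(rp, 3)), 0)

  a <- gen_ecg(512, 120, list(type = "constant", rr_s = 1),
               asystoles = data.frame(start = 50, duration = 10), seed = 25)
  ev <- detect_asystole(detect_r_peaks(a$signal, 512), 5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 10, tolerance = 0.1 / 10)
  empty <- structure(list(times = numeric(0), amplitudes = numeric(0)),
                     class = "rpeak_series")
  expect_equal(nrow(detect_asystole(empty, 5)), 0)
})

test_that("the electrocardiomatrix is shape-correct, sorted and aligned", {
  e <- gen_ecg(512, 60, list(type = "constant", rr_s = 1), seed = 26)
  rp <- detect_r_peaks(e$signal, 512)
  ecm <- build_ecm(e$signal, rp, half_window = 0.4, fs = 512)
  hw <- round(0.4 * 512)
  expect_equal(ncol(ecm$matrix), 2 * hw + 1)
  expect_equal(nrow(ecm$matrix) + ecm$n_dropped, length(rp$times))
  expect_false(is.unsorted(ecm$beat_times))
  # rows centred on the R wave
  centre <- hw + 1
  offs <- apply(ecm$matrix, 1, which.max) - centre
  expect_lte(max(abs(offs)), 1)
  # constant rhythm: adjacent rows nearly identical
  cors <- vapply(seq_len(nrow(ecm$matrix) - 1),
                 function(i) cor(ecm$matrix[i, ], ecm$matrix[i + 1, ]), 1)
  expect_gt(min(cors), 0.99)
  expect_error(build_ecm(e$signal[1:600], rp, half_window = 5, fs = 512),
               "window")
})

test_that("stage tables pass through explicit intervals and detect suppression", {
  st <- stage_table(c("S1", "S2"), c(0, 120), c(120, 300))
  out <- build_stage_table(intervals = st)
  expect_equal(out$label, st$label)
  expect_equal(out$end, st$end)
  expect_error(build_stage_table(
    intervals = data.frame(label = c("S1", "S2"),
                           start = c(0, 100), end = c(150, 200))),
    "overlap")

  # EEG amplitude drops to 10% at t = 300 with withdrawal annotated at 120:
  # S2 must end near the suppression onset
  fs <- 64
  withr::with_seed(30, {
    n <- fs * 360
    amp <- c(rep(1, fs * 300), rep(0.1, n - fs * 300))
    sig <- rbind(amp * rnorm(n, sd = 20), amp * rnorm(n, sd = 20))
  })
  rec <- recording(sig, fs, c("C3", "C4"),
                   annotations = data.frame(time = 120,
                                            text = "ventilator withdrawal"))
  st2 <- build_stage_table(rec)
  expect_equal(st2$label, c("S1", "S2"))
  expect_equal(st2$start[2], 120)
  expect_lt(abs(st2$end[2] - 300), 15)
  expect_error(build_stage_table(make_test_recording()), "annotation")
})
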