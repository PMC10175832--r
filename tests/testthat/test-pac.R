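# Modulation index, phase/amplitude extraction, comodulograms, PAC matrices,
# surrogate thresholds.

test_that("modulation index hits its limits and matches a brute-force oracle", {
  withr::with_seed(1, {
    phase <- runif(20000, -pi, pi)
    # constant envelope -> uniform P -> MI = 0
    expect_equal(modulation_index(phase, rep(2.5, length(phase))), 0)
    # envelope confined to one bin -> MI = 1
    amp1 <- ifelse(phase > 0 & phase <= pi / 9, 1, 0)
    expect_equal(suppressWarnings(modulation_index(phase, amp1)), 1)
    # cosine-modulated envelope equals the direct histogram computation
    amp <- 1 + 0.5 * cos(phase)
    expect_equal(modulation_index(phase, amp), mi_brute(phase, amp),
                 tolerance = 1e-12)
    # random envelopes agree with the oracle too
    for (k in 1:3) {
      a <- abs(rnorm(length(phase)))
      expect_equal(modulation_index(phase, a), mi_brute(phase, a),
                   tolerance = 1e-12)
    }
    expect_error(modulation_index(phase, numeric(0)), "length")
    expect_error(modulation_index(phase, rep(0, length(phase))), "amplitude")
  })
})

test_that("MI is invariant to amplitude rescaling and phase offset", {
  withr::with_seed(2, {
    phase <- runif(50000, -pi, pi)
    amp <- 1 + 0.6 * cos(phase) + abs(rnorm(length(phase), sd = 0.1))
    m0 <- modulation_index(phase, amp)
    expect_equal(modulation_index(phase, 37.5 * amp), m0, tolerance = 1e-12)
    shifted <- ((phase + 1.1 + pi) %% (2 * pi)) - pi
    expect_lt(abs(modulation_index(shifted, amp) - m0), 1e-3)
  })
})

test_that("phase extraction tracks a tone and is uniform off-band", {
  fs <- 512
  tt <- (0:(fs * 20 - 1)) / fs
  x <- sin(2 * pi * 10 * tt)
  ph <- extract_phase(x, fs, c(9, 11))
  mid <- (fs * 2):(fs * 18)
  slope <- mean(diff(unwrap_phase <- cumsum(c(ph[mid[1]],
    ((diff(ph[mid]) + pi) %% (2 * pi)) - pi))))
  expect_lt(abs(slope * fs - 2 * pi * 10) / (2 * pi * 10), 0.001)

  withr::with_seed(4, noisy <- x + rnorm(length(x), sd = 0.1))
  phn <- extract_phase(noisy, fs, c(9, 11))
  expect_gt(cor(cos(phn[mid]), cos(ph[mid])), 0.99)

  # band not containing the tone: phase histogram is consistent with uniform
  withr::with_seed(5, off <- sin(2 * pi * 10 * tt) + rnorm(length(tt)))
  pho <- extract_phase(off, fs, c(30, 34))
  h <- table(cut(pho[mid], seq(-pi, pi, length.out = 19)))
  expect_gt(chisq.test(as.vector(h))$p.value, 0.01)
  expect_error(extract_phase(x, fs, c(10, 10.1)), "narrow")
})

test_that("amplitude extraction recovers envelopes", {
  fs <- 512
  tt <- (0:(fs * 20 - 1)) / fs
  mid <- (fs * 2):(fs * 18)
  flat <- extract_amplitude(sin(2 * pi * 40 * tt), fs, c(35, 45))
  expect_lt(max(abs(flat[mid] - 1)), 0.02)
  env <- 1 + 0.5 * sin(2 * pi * 5 * tt)
  am <- extract_amplitude(env * sin(2 * pi * 40 * tt), fs, c(25, 55))
  expect_lt(sqrt(mean((am[mid] - env[mid])^2)) / mean(env), 0.02)
  expect_equal(max(extract_amplitude(numeric(fs * 10), fs, c(35, 45))), 0)
})

test_that("comodulogram masks invalid cells and rejects short windows", {
  x <- gen_pac_signal(512, 8, 6, 60, 0.5, seed = 6)
  cm <- comodulogram(x, fs = 512, phase_freqs = c(4, 8), amp_freqs = c(6, 12, 80))
  expect_true(is.na(cm$mi["8", "6"]))     # amp band overlaps phase band
  expect_false(is.na(cm$mi["4", "80"]))
  expect_error(comodulogram(x[1:512], fs = 512, phase_freqs = c(2, 4)),
               "5 cycles")
})

test_that("surrogate threshold calibrates and flags strong coupling", {
  # quantile convention: alpha = 1 -> threshold is the minimum surrogate
  withr::with_seed(7, {
    phase <- runif(4096, -pi, pi)
    amp <- abs(rnorm(4096)) + 0.5
    st <- pac_surrogate_threshold(phase, amp, fs = 512,
                                  pac_params(n_surrogates = 100, alpha = 1 - 1e-9))
    expect_equal(st$threshold, min(st$surrogates))
  })
  # strong stochastic-modulator coupling is far above the surrogate cloud
  x <- gen_pac_signal(512, 60, 10, 80, 0.9, phase_drift = 0.03, seed = 8)
  ph <- extract_phase(x, 512, c(9, 11))
  am <- extract_amplitude(x, 512, c(65, 95))
  st <- pac_surrogate_threshold(ph, am, fs = 512, pac_params(n_surrogates = 200))
  expect_gte(st$z, 5)
  expect_gt(st$observed, st$threshold)
  expect_error(pac_surrogate_threshold(ph[1:600], am[1:600], fs = 512),
               "short")
  expect_error(pac_surrogate_threshold(ph, am, fs = 512,
                                       pac_params(n_surrogates = 50)),
               "100")
})

test_that("PAC matrix restricts amplitude bands to gamma and localizes links", {
  spec <- session_spec(seed = 3)
  spec$stages <- list(spec$stages[[2]])   # surge stage only, 90 s
  sess <- gen_session(spec)
  rec <- sess$recording
  expect_error(band_pac_matrix(rec, phase_band = "delta", amp_band = "alpha"),
               "gamma")
  m <- band_pac_matrix(rec, phase_band = "beta", amp_band = "gamma2",
                       phase_channels = c("C3", "C4", "P3", "O1"))
  vals <- diag(m$values)
  expect_equal(names(which.max(vals)), "C4")
  expect_gte(max(vals), 3 * sort(vals, decreasing = TRUE)[2])
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("cross-regional PAC recovers a frontal-phase/posterior-amp link", {
  spec <- session_spec(seed = 9)
  spec$stages <- list(list(
    label = "S2", duration = 60,
    amps = list(default = c(delta = 20, theta = 10, alpha = 8, beta = 4,
                            gamma1 = 0.5, gamma2 = 0.3)),
    noise_sd = 5,
    pac_links = list(list(phase_ch = "F8", amp_ch = "C4",
                          phase_band = "beta", amp_band = "gamma2",
                          chi = 0.9, amp = 10))))
  sess <- gen_session(spec)
  m <- band_pac_matrix(sess$recording, phase_band = "beta", amp_band = "gamma2",
                       mode = "cross",
                       phase_channels = c("F7", "F8"),
                       amp_channels = c("C3", "C4", "P4"))
  idx <- which(m$values == max(m$values), arr.ind = TRUE)
  expect_equal(rownames(m$values)[idx[1]], "F8")
  expect_equal(colnames(m$values)[idx[2]], "C4")
  expect_error(band_pac_matrix(sess$recording, phase_band = "beta",
                               amp_band = "gamma2", mode = "cross",
                               phase_channels = "O1"),
               "prefrontal")
})
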