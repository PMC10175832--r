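# Synthetic EEG/ECG sessions with known ground truth: per-stage band
# amplitudes, injected phase-amplitude coupling, coherent and lag-directed
# channel links, and an ECG with a controllable heart-rate trajectory, RR
# variability and asystole events. Every pipeline stage is testable against
# the generator's parameters without any recorded data.

#' Synthetic phase-amplitude-coupled signal
#'
#' `x(t) = sin(2 pi f_phase t) +
#'   [1 - chi + chi (1 + sin(2 pi f_phase t)) / 2] sin(2 pi f_amp t) + eps(t)`
#' so the fast oscillation's envelope follows the slow phase with strength
#' `chi`; `chi = 0` makes the envelope constant (no coupling), `chi = 1`
#' modulates it fully.
#'
#' @param fs sampling rate, Hz.
#' @param dur duration, s.
#' @param f_phase,f_amp slow and fast frequencies, Hz (`f_phase < f_amp <
#'   fs/2`).
#' @param chi coupling strength in \[0,1\].
#' @param noise_sd white-noise SD.
#' @param phase_drift random-walk SD (rad per sample) added to the slow
#'   phase. The default 0 keeps the modulator strictly periodic. A small
#'   drift (~0.01) makes the slow phase wander so that circular time-shift
#'   surrogates genuinely destroy the coupling — for a strictly periodic
#'   modulator a time shift is only a constant phase offset, which the
#'   modulation index ignores, so surrogate significance tests need the
#'   stochastic variant.
#' @param seed optional seed (restores the caller's RNG state).
#' @return Numeric signal of `fs * dur` samples.
#' @export
gen_pac_signal <- function(fs, dur, f_phase, f_amp, chi, noise_sd = 0.1,
                           phase_drift = 0, seed = NULL) {
  if (!(f_phase < f_amp && f_amp < fs / 2))
    stop_("need f_phase < f_amp < fs/2 (got %g, %g at fs %g)", f_phase, f_amp, fs)
  if (chi < 0 || chi > 1) stop_("chi must lie in [0,1]")
  with_seed(seed, {
    t <- (0:(fs * dur - 1)) / fs
    phi <- 2 * pi * f_phase * t
    if (phase_drift > 0) phi <- phi + cumsum(rnorm(length(t), sd = phase_drift))
    slow <- sin(phi)
    env <- 1 - chi + chi * (1 + slow) / 2
    slow + env * sin(2 * pi * f_amp * t) + rnorm(length(t), sd = noise_sd)
  })
}

#' Synthetic coherent signal pair
#'
#' Two signals sharing a common band-limited component around `f` with
#' independent band-limited noise: `x = sqrt(snr) s + n1`,
#' `y = sqrt(snr) s + n2`, all components unit variance in the band, so the
#' in-band magnitude-squared coherence is analytically
#' `(snr / (1 + snr))^2`.
#'
#' @param fs sampling rate, Hz.
#' @param dur duration, s.
#' @param f shared-component centre frequency, Hz.
#' @param snr shared-to-independent power ratio in the band (0 = independent;
#'   large values drive coherence to 1).
#' @param bw band width of all components, Hz (default 2).
#' @param seed optional seed.
#' @return List with `x`, `y` and the shared component `s`.
#' @export
gen_coherent_pair <- function(fs, dur, f, snr, bw = 2, seed = NULL) {
  if (snr < 0) stop_("snr must be non-negative")
  with_seed(seed, {
    n <- round(fs * dur)
    lo <- max(f - bw / 2, 0.5); hi <- f + bw / 2
    s <- bandlimited_noise(n, fs, lo, hi)
    n1 <- bandlimited_noise(n, fs, lo, hi)
    n2 <- bandlimited_noise(n, fs, lo, hi)
    g <- sqrt(min(snr, 1e12))
    list(x = g * s + n1, y = g * s + n2, s = s)
  })
}

#' Synthetic directed (lagged) signal pair
#'
#' `y(t) = gain * x(t - lag) + eta(t)` with `x` and `eta` independent
#' band-limited unit-variance noise, so information flows x -> y only.
#'
#' @param fs sampling rate, Hz.
#' @param dur duration, s.
#' @param band band specification for all components.
#' @param lag lag in seconds (negative values reverse the direction).
#' @param gain coupling gain (0 = independent pair).
#' @param seed optional seed.
#' @return List with `x`, `y` and `lag_samples`.
#' @export
gen_directed_pair <- function(fs, dur, band, lag, gain, seed = NULL) {
  band <- as_band(band)
  with_seed(seed, {
    n <- round(fs * dur)
    L <- round(abs(lag) * fs)
    src <- bandlimited_noise(n + L, fs, band$lo, band$hi)
    eta <- bandlimited_noise(n, fs, band$lo, band$hi)
    x_full <- src[(L + 1L):(L + n)]
    lagged <- src[1:n]
    out <- list(x = x_full, y = gain * lagged + eta, lag_samples = L)
    if (lag < 0) out <- list(x = out$y, y = out$x, lag_samples = L)
    out
  })
}

qrs_template <- function(fs, width_s = 0.04, amp_uV = 1000) {
  sigma <- width_s / 4
  half <- round(4 * sigma * fs)
  u <- (-half:half) / fs            # sample-aligned so the peak sits on u = 0
  # derivative-of-Gaussian, shifted so the positive (R) peak sits at u = 0
  g <- -(u - sigma) * exp(-(u - sigma)^2 / (2 * sigma^2))
  amp_uV * g / max(g)
}

# Beat times from an RR model over [0, dur): constant RR, a linear heart-rate
# ramp, or Gaussian RR jitter. An asystole stops the heart on a beat at its
# start and resumes with a beat at its end, so the RR gap equals the
# configured duration exactly.
rr_beat_times <- function(dur, rr_model, asystoles = NULL) {
  if (is.null(asystoles)) asystoles <- data.frame(start = numeric(0),
                                                 duration = numeric(0))
  t <- 0.5
  beats <- numeric(0)
  while (t < dur - 0.2) {
    k <- which(t >= asystoles$start & t < asystoles$start + asystoles$duration)
    if (length(k)) {
      k <- k[1]
      if (!length(beats) || asystoles$start[k] - beats[length(beats)] > 0.3)
        beats <- c(beats, asystoles$start[k])
      t <- asystoles$start[k] + asystoles$duration[k]
      next
    }
    beats <- c(beats, t)
    rr <- switch(rr_model$type,
      constant = rr_model$rr_s,
      ramp = {
        hr <- rr_model$hr_from + (rr_model$hr_to - rr_model$hr_from) * t / dur
        60 / hr
      },
      gaussian = max(0.3, rnorm(1, rr_model$mean_rr_s, rr_model$sd_ms / 1000)),
      stop_("unknown RR model '%s'", rr_model$type))
    t <- t + rr
  }
  beats
}

#' Synthetic ECG signal
#'
#' A QRS template (derivative-of-Gaussian, 40 ms wide, 1 mV, R peak at the
#' beat time) placed at beat times drawn from an RR model, with silence
#' during asystole events and a small additive baseline noise.
#'
#' @param fs sampling rate, Hz.
#' @param dur duration, s.
#' @param rr_model list: `list(type = "constant", rr_s = )`,
#'   `list(type = "ramp", hr_from = , hr_to = )` (bpm, linear over `dur`), or
#'   `list(type = "gaussian", mean_rr_s = , sd_ms = )`.
#' @param asystoles data.frame with `start` and `duration` (s), or `NULL`.
#' @param noise_sd baseline noise SD in uV (default 2).
#' @param seed optional seed.
#' @return List with `signal` (uV), `beat_times` (s, ground truth) and
#'   `asystoles`.
#' @export
gen_ecg <- function(fs, dur, rr_model = list(type = "constant", rr_s = 1),
                    asystoles = NULL, noise_sd = 2, seed = NULL) {
  with_seed(seed, {
    n <- round(fs * dur)
    beats <- rr_beat_times(dur, rr_model, asystoles)
    x <- rnorm(n, sd = noise_sd)
    tpl <- qrs_template(fs)
    half <- (length(tpl) - 1L) %/% 2L
    for (b in beats) {
      c0 <- round(b * fs) + 1L
      lo <- c0 - half; hi <- c0 + (length(tpl) - 1L - half)
      if (lo < 1L || hi > n) next
      x[lo:hi] <- x[lo:hi] + tpl
    }
    list(signal = x, beat_times = (round(beats * fs)) / fs,
         asystoles = asystoles)
  })
}

#' Default synthetic session specification
#'
#' A three-stage session emulating the canonical terminal-recording scenario:
#' a quiet-gamma comatose baseline (S1); a post-withdrawal surge stage (S2)
#' with gamma power at F7/F8/C3/C4, beta-phase/gamma2-amplitude coupling at
#' C4 and coherent gamma1 links within the left TPO junction; and a late
#' stage (S3) carrying a contralateral posterior-to-frontal directed gamma1
#' link (T5 -> F4). The ECG runs a jittered 70-bpm rhythm with one 10-s
#' asystole inside S3.
#'
#' @param fs sampling rate, Hz (default 512).
#' @param seed session seed (default 1).
#' @return A list of class `session_spec` consumed by [gen_session()].
#' @export
session_spec <- function(fs = 512, seed = 1) {
  quiet <- c(delta = 20, theta = 10, alpha = 8, beta = 4,
             gamma1 = 0.5, gamma2 = 0.3)
  surge_ch <- c("F7", "F8", "C3", "C4")
  surge <- quiet; surge["gamma1"] <- 15; surge["gamma2"] <- 10
  structure(list(
    fs = fs, seed = seed,
    stages = list(
      list(label = "S1", duration = 60, amps = list(default = quiet),
           noise_sd = 5),
      list(label = "S2", duration = 90,
           amps = c(list(default = quiet),
                    setNames(rep(list(surge), length(surge_ch)), surge_ch)),
           noise_sd = 5,
           pac_links = list(list(channel = "C4", phase_band = "beta",
                                 amp_band = "gamma2", chi = 0.8, amp = 10)),
           coh_links = list(
             # one source driving the whole left TPO triangle: pairwise
             # independent sources would triple each channel's in-band power
             # and dilute every pair's coherence
             list(channels = c("O1", "P3", "T5"), band = "gamma1",
                  gain = 4))),
      list(label = "S3", duration = 60, amps = list(default = quiet),
           noise_sd = 5,
           dir_links = list(list(src = "T5", tgt = "F4", band = "gamma1",
                                 lag_s = 0.006, gain = 3)))),
    ecg = list(rr_model = list(type = "gaussian", mean_rr_s = 60 / 70,
                               sd_ms = 30),
               asystoles = data.frame(start = 170, duration = 10))),
    class = "session_spec")
}

stage_amp_for <- function(stage, ch) {
  a <- stage$amps[[ch]] %||% stage$amps$default
  if (is.null(a)) stop_("stage '%s': no amplitude table for %s", stage$label, ch)
  a
}

#' Generate a synthetic session
#'
#' Renders a `session_spec` into a 20-channel recording (19 EEG channels of
#' the 10/20 montage plus ECG), a stage table, and a ground-truth record.
#' Each EEG channel is 1/f-shaped background noise plus unit-variance
#' band-limited components scaled to the stage's per-band RMS amplitudes;
#' PAC, coherence and directed links are injected additively per the spec.
#' Fixing the seed makes the output byte-identical across runs.
#'
#' @param spec a [session_spec()] (or a compatible list).
#' @return List with `recording`, `stages` (a `stage_table`) and `truth`
#'   (versioned ground-truth record: links, ECG beat times, asystoles, seed).
#' @export
gen_session <- function(spec = session_spec()) {
  fs <- spec$fs
  durs <- vapply(spec$stages, `[[`, 1, "duration")
  if (any(durs <= 0)) stop_("stage durations must be positive")
  labels <- vapply(spec$stages, `[[`, "", "label")
  if (anyDuplicated(labels)) stop_("duplicate (overlapping) stage definitions")
  total <- sum(durs)
  chans <- CHANNELS_1020
  bands <- eeg_bands()
  with_seed(spec$seed, {
    sig <- matrix(0, length(chans) + 1L, round(total * fs))
    offset <- 0L
    for (st in spec$stages) {
      n <- round(st$duration * fs)
      idx <- (offset + 1L):(offset + n)
      tt <- (0:(n - 1)) / fs
      for (ci in seq_along(chans)) {
        amps <- stage_amp_for(st, chans[ci])
        x <- (st$noise_sd %||% 5) * pink_noise(n, fs)
        for (b in names(amps)) {
          if (amps[[b]] <= 0) next
          bd <- bands[[b]]
          x <- x + amps[[b]] * bandlimited_noise(n, fs, max(bd$lo, 0.5), bd$hi)
        }
        sig[ci, idx] <- x
      }
      for (lk in st$pac_links %||% list()) {
        pb <- as_band(lk$phase_band); ab <- as_band(lk$amp_band)
        fp <- (pb$lo + pb$hi) / 2; fa <- (ab$lo + ab$hi) / 2
        slow <- sin(2 * pi * fp * tt)
        fast <- (1 - lk$chi + lk$chi * (1 + slow) / 2) * sin(2 * pi * fa * tt)
        if (!is.null(lk$channel)) {
          ci <- match(lk$channel, chans)
          sig[ci, idx] <- sig[ci, idx] + lk$amp * (slow + fast)
        } else {
          pi_ <- match(lk$phase_ch, chans); ai <- match(lk$amp_ch, chans)
          sig[pi_, idx] <- sig[pi_, idx] + lk$amp * slow
          sig[ai, idx] <- sig[ai, idx] + lk$amp * fast
        }
      }
      for (lk in st$coh_links %||% list()) {
        bd <- as_band(lk$band)
        shared <- bandlimited_noise(n, fs, bd$lo, bd$hi)
        for (ch in lk$channels %||% c(lk$a, lk$b)) {
          ci <- match(ch, chans)
          sig[ci, idx] <- sig[ci, idx] + lk$gain * shared
        }
      }
      for (lk in st$dir_links %||% list()) {
        bd <- as_band(lk$band)
        L <- round(lk$lag_s * fs)
        comp <- bandlimited_noise(n + L, fs, bd$lo, bd$hi)
        si <- match(lk$src, chans); ti <- match(lk$tgt, chans)
        sig[si, idx] <- sig[si, idx] + lk$gain * comp[(L + 1L):(L + n)]
        sig[ti, idx] <- sig[ti, idx] + lk$gain * comp[1:n]
      }
      offset <- offset + n
    }
    ecg <- gen_ecg(fs, total, spec$ecg$rr_model, spec$ecg$asystoles)
    sig[length(chans) + 1L, ] <- ecg$signal
    ends <- cumsum(durs)
    ann <- data.frame(time = ends[1], text = "ventilator withdrawal")
    rec <- recording(sig, fs, c(chans, "ECG"), reference = "as-recorded",
                     annotations = ann)
    stages <- stage_table(labels, c(0, head(ends, -1)), ends)
    truth <- list(
      schema_version = "1.0", fs = fs, seed = spec$seed,
      stages = lapply(spec$stages, function(st)
        st[intersect(names(st), c("label", "duration", "pac_links",
                                  "coh_links", "dir_links"))]),
      ecg_beat_times = ecg$beat_times,
      asystoles = spec$ecg$asystoles)
    list(recording = rec, stages = stages, truth = truth)
  })
}
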