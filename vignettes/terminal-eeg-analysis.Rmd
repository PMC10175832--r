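---
title: "Band power, cross-frequency coupling and directed connectivity in terminal EEG/ECG recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band power, cross-frequency coupling and directed connectivity in terminal EEG/ECG recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegconn)
```

## What this package computes

`eegconn` analyzes multichannel scalp EEG (19 electrodes of the international
10/20 system, originally Fpz-referenced) recorded together with one ECG
channel, across clinically defined stages of a recording — typically a
comatose baseline (S1), the period from withdrawal of ventilatory support to
acute EEG suppression (S2), and later stages delimited by cardiac features.
Five families of measures are computed per stage:

1. **Band power** — short-time Fourier spectrograms (2-s Hann epochs, 1-s
   overlap) integrated over six bands: delta [0,4), theta [4,8), alpha
   [8,13), beta [13,25), gamma1 [25,55) and gamma2 [80,150) Hz, and
   between-stage fold changes per channel. The 55–80 Hz gap deliberately
   brackets the 60 Hz mains region.
2. **Phase–amplitude coupling (PAC)** — the entropy-based modulation index
   (MI): phases of a slow band and amplitude envelopes of a fast band are
   extracted with zero-phase FIR band-passes and the analytic signal; the
   phase axis is divided into 18 equal bins; the normalized mean-amplitude
   distribution `P` gives `MI = (log 18 − H(P)) / log 18`. Computed as
   comodulograms over (phase 1–50 Hz) × (amplitude 2–256 Hz) grids, as
   per-electrode ("local") matrices, and as cross-regional matrices with
   prefrontal phase and posterior amplitude channels.
3. **Functional connectivity** — Welch magnitude-squared coherence (2-s Hann
   segments, 50 % overlap), averaged over in-band bins for every channel
   pair, with summaries over the temporo-parieto-occipital (TPO) junctions
   (O1P3, O1T5, P3T5 left; O2P4, O2T6, P4T6 right), long-range
   posterior–frontal pairs tagged ipsi/contra by 10/20 odd/even parity, and
   classical pooled-variance t contrasts.
4. **Directed connectivity** — normalized symbolic transfer entropy (NSTE):
   ordinal (rank-pattern) symbolization with embedding dimension `d = 3`,
   plug-in transfer entropy over `(y_{t+δ}, y_t, x_t)` triples, bias
   subtraction by source-shuffled surrogates, normalization by the target's
   conditional entropy `H(y_future | y_past)`, clipped to [0,1].
   Feedforward/feedback summaries average posterior→frontal and
   frontal→posterior entries.
5. **ECG staging features** — R-peak detection by an adaptive ("variable")
   threshold, RR intervals, SDNN, mean heart rate, asystole detection as
   long inter-peak gaps, and the electrocardiomatrix (ECM): beat-centred ECG
   epochs stacked in R-peak time order.

A seeded synthetic-session generator supplies ground truth for every one of
these measures, so the whole pipeline is testable without patient data.

## Preprocessing model and assumptions

Recordings are assumed to arrive in EDF/EDF+ at a common sampling rate
(512 Hz in the motivating data). Channel labels are normalized through an
alias table (T7↔T3, T8↔T4, P7↔T5, P8↔T6; ECG/EKG→ECG). EEG channels are
re-referenced to the common average — the mean over EEG channels is
subtracted at every sample; the ECG never participates. Mains interference
is removed with second-order IIR notches (quality factor 30) at 60 Hz and
every harmonic below Nyquist, applied forward–backward so there is no group
delay. Re-referencing and notch filtering are both linear and time-invariant
across channels, so they commute; the test suite asserts this.

One caveat worth knowing: with a common-average reference, a very large
signal on a few channels leaks (with opposite sign) into all the others
through the subtracted mean. This is a property of the montage, not a bug;
it slightly inflates baseline coherence everywhere when a strong focal surge
is present. The synthetic default session makes this visible: quiet-channel
coherence in the surge stage sits near 0.2 while the injected TPO link
exceeds 0.6.

## Tunable parameters that matter

| Parameter | Default | Why |
|---|---|---|
| spectrogram epoch / overlap | 2 s / 1 s | 0.5 Hz grid; matches the stage maps |
| stage-level power aggregate | median over epochs | robust to brief transients; mean available |
| MI phase bins | 18 | the standard entropy-MI convention |
| phase filter bandwidth | 2 Hz (< 20 Hz), 4 Hz above | narrow enough to define a phase |
| amplitude filter bandwidth | ≥ 3 × phase frequency | side-bands at ±f_p must pass at full gain; with a 2 f_p band the FIR transition skirts clip them and MI collapses (measured, not assumed) |
| FIR order | 3 cycles of min(low edge, bandwidth/4) | sharp enough that a strong neighbouring oscillation cannot leak through the stopband of a narrow high-frequency band |
| PAC / NSTE windows | 30 s, 15-s hop, median | one stage value robust to nonstationarity |
| surrogates | ≥ 100 circular shifts ≥ 1 s | preserves both marginals, breaks alignment |
| NSTE | d = 3, τ = quarter cycle of band centre, δ = τ, 20 shuffles | standard ordinal-TE practice; all config-exposed |
| Welch coherence | 2-s Hann, 50 % overlap, ≥ 8 segments | single-segment MSC is identically 1 |
| coherence cap | 150 Hz | band summaries never cross the cap |
| R-peak threshold | ½ × rolling 2-s max, floored at 3 × MAD | adapts to amplitude decline near death |
| refractory | 0.2 s | physiological upper rate bound |
| SDNN | population SD over all detected beats | dying-phase ECG: no NN filtering (switchable) |
| ECM half-window | 1.5 s | shows P-QRS-T plus neighbouring beats |
| asystole | inter-peak gap ≥ threshold | a gap criterion, not a flat-line criterion |

## Numerical choices and degenerate inputs

* Phase bins are half-open over (−π, π]; a phase of exactly −π folds into the
  first bin. Empty bins set `P = 0`, are flagged, and are never smoothed.
* A constant envelope gives MI = 0 and an envelope confined to one bin gives
  MI = 1, exactly; an all-zero envelope is an error.
* Comodulogram cells whose amplitude band reaches down into the phase band
  are reported as `NA` (absent), not zero.
* The surrogate threshold uses the type-1 empirical quantile, so `alpha = 1`
  returns the minimum surrogate.
* Ordinal ties are broken earlier-index-smaller, so a constant signal maps to
  a single valid symbol and is flagged.
* `t = 0, p = 1` is returned for degenerate zero-variance equal-mean
  contrasts instead of `NaN`.
* Fold-change denominators can be floored at a configurable ε, with the
  floored channels flagged; a zero denominator without ε is an error.
* Re-referencing an already average-referenced recording is an error, not a
  silent no-op.
* When a record is too short to carry the ideal FIR order, the order degrades
  gracefully to a third of the record length (never below 16 taps) instead of
  refusing the analysis; genuinely unusable records still error.

## The surrogate test and periodic modulators

Circular time-shift surrogates rotate the amplitude series by ≥ 1 s and
re-measure MI. For any *strictly periodic* modulator this is provably blind:
a time shift of a sinusoidal envelope is a constant phase offset of the
modulation, and MI is invariant to constant phase offsets (it only relabels
bins). The synthetic coupled signal `gen_pac_signal()` has exactly such a
sinusoidal modulator, so its coupling — however strong — is *correctly* not
separable from its own time-shifts. The generator therefore exposes a
`phase_drift` parameter (default 0 keeps the strictly periodic form): a
small phase random walk (≈ 0.03 rad/sample at 512 Hz) makes the slow phase
wander the way real slow oscillations do, after which strong coupling stands
5–8 standard deviations above the surrogate cloud while the null calibration
(≈ 5 % exceedance at α = 0.05) is unchanged. Real EEG is never strictly
periodic, so this is a property of the synthetic edge case, not of the
method.

## What the synthetic generator emulates — and what it does not

Each EEG channel is 1/f-shaped background noise plus unit-variance
band-limited components scaled to per-stage RMS amplitudes (band-limited
noise is synthesized spectrally — FFT masking of white noise — which is
exactly band-limited and fast at session scale). On top of this the
generator injects: sinusoidally coupled phase/amplitude pairs at chosen
electrodes (strength χ ∈ [0,1]), shared band-limited sources across chosen
electrode groups (coherence links), lagged copies between electrode pairs
(directed links), and an ECG built from a 40-ms derivative-of-Gaussian QRS
template placed at RR-model beat times, with silence during asystole events.
The default session renders a three-stage scenario: quiet-gamma baseline;
a surge stage with gamma power at F7/F8/C3/C4, beta/gamma2 PAC at C4 and a
single shared gamma1 source across the left TPO triangle (one source, not
three pairwise ones — pairwise-independent sources would triple each
channel's in-band power and dilute every pair's coherence); and a late stage
with a contralateral T5→F4 directed gamma1 link plus a 10-s asystole.

The generator does **not** emulate: volume conduction and realistic source
mixing, muscle/movement artifact, electrode pops, burst-suppression
morphology, pacemaker spikes, or nonstationarity within a stage. Passing
tests therefore demonstrate that the estimators recover known structure
under realistic spectra and noise levels — not that they are robust to every
artifact class of clinical EEG.

## Stage tables

Explicit stage tables (CSV `label,start_s,end_s`) always pass through
verbatim after validation. When only a ventilator-withdrawal annotation is
available, S2 is bounded by the annotation time and the first time the 30-s
moving RMS of the broadband EEG falls below 25 % of the baseline RMS (the
acute suppression). Stages beyond S2 always require explicit intervals: the
cardiac criteria that delimit them in practice are patient-specific and are
supplied as configuration, not guessed.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run at the study's sampling rate
(512 Hz) with 60-s PAC windows, 20-s directed-pair windows, 100–200 seeded
replicates for calibration/recovery rates, a 210-s three-stage default
session, and 240-s ECG records for SDNN recovery. These sizes give stable
rates while keeping a full run in the minutes range on one core.

## Known limitations

* MSC has a positive bias of order 1/K for K averaged segments; short stages
  (few segments) therefore overstate weak coherence. The 8-segment minimum
  bounds this at ~12 %.
* Plug-in TE is biased upward for undersampled symbol distributions; the
  shuffle term removes most of it, and results from fewer than `10·(d!)²`
  triples carry an `undersampled` flag.
* The local-PAC matrix is diagonal by construction (phase and amplitude from
  the same electrode); cross-regional mode is restricted to prefrontal
  phase × posterior amplitude channels.
* EDF support covers 16-bit EDF/EDF+C with per-signal scaling and TAL
  annotations — enough for polygraphic EEG/ECG exports, not a general EDF
  library.
* Midline electrodes (Fz, Cz, Pz) are retained in the data model but
  excluded from topographic summaries and hemispheric contrasts.
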