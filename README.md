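# eegconn

Band power, cross-frequency coupling, functional and directed connectivity,
and ECG-based staging for multichannel EEG/ECG recordings — built for the
analysis of terminal recordings in which a comatose baseline (S1), the
period after withdrawal of life support (S2), and later cardiac-defined
stages are compared electrode by electrode.

## The measures

For a recording with 19 scalp electrodes (10/20 montage) plus ECG, split
into stages, the package computes per stage and frequency band (delta 0–4,
theta 4–8, alpha 8–13, beta 13–25, gamma1 25–55, gamma2 80–150 Hz):

* **Band power and fold change** — short-time DFT spectrograms (2-s Hann
  epochs, 1-s overlap, one-sided density), band-integrated power per channel,
  and between-stage ratios `fold = P_S2 / P_S1`.
* **Phase–amplitude coupling** — the entropy-based modulation index. With
  phases φ(t) of a slow band binned into N = 18 equal bins and the fast
  band's envelope A(t) averaged per bin and normalized to a distribution P,

      MI = (log N − H(P)) / log N,   H(P) = −Σ P_j log P_j

  so MI = 0 for phase-independent amplitude and MI = 1 when all amplitude
  falls in one phase bin. Comodulograms, per-electrode matrices,
  cross-regional (prefrontal-phase × posterior-amplitude) matrices, and
  circular-shift surrogate thresholds are provided.
* **Coherence** — Welch magnitude-squared coherence
  `|S_xy|² / (S_xx S_yy)` with 2-s Hann segments at 50 % overlap, averaged
  over in-band bins, with temporo-parieto-occipital (TPO) junction
  summaries and pooled-variance t contrasts.
* **Directed connectivity** — normalized symbolic transfer entropy:
  ordinal symbols (d = 3 rank patterns), plug-in transfer entropy

      TE(x→y) = Σ p(y⁺, y, x) log₂ [ p(y⁺ | y, x) / p(y⁺ | y) ]

  bias-corrected by source-shuffled surrogates and normalized by
  H(y⁺ | y), clipped to [0,1]; feedforward/feedback summaries between TPO
  and prefrontal electrode sets.
* **ECG staging** — adaptive-threshold R-peak detection, RR/SDNN heart-rate
  variability, asystole detection as inter-peak gaps, and the
  electrocardiomatrix (beat-centred epochs stacked in R-peak time order).

A seeded synthetic-session generator (`session_spec()` / `gen_session()`)
renders 20-channel recordings with known injected structure — per-stage band
amplitudes, PAC links, coherent sources, lagged directed links, and a
controllable ECG — so every stage of the pipeline is testable without any
recorded data. EDF/EDF+ reading and writing, stage-table CSVs, tidy CSV
outputs and a JSON run manifest are included.

## Worked example

```r
library(eegconn)

sess <- gen_session(session_spec(seed = 1))   # 3-stage synthetic session
rec  <- notch_filter(average_rereference(sess$recording))

# gamma1 power fold change, surge stage over baseline
m <- band_power_map(rec, sess$stages, "gamma1",
                    channels = c("F7", "F8", "C3", "C4"))
round(fold_change(m, stage_num = "S2", stage_den = "S1"), 1)
#>   F7   F8   C3   C4
#> 59.7 61.8 57.7 59.5

# beta-phase / gamma2-amplitude PAC at the somatosensory electrodes
p2 <- band_pac_matrix(rec, sess$stages, "S2", "beta", "gamma2")
which.max(diag(p2$values))                     # C4 carries the injected link
#> C4
#> 11

# left TPO gamma1 coherence, S2 vs S1
c1 <- tpo_summary(band_coherence(rec, sess$stages, "S1", "gamma1"), "left")
c2 <- tpo_summary(band_coherence(rec, sess$stages, "S2", "gamma1"), "left")
round(c(S1 = c1$mean, S2 = c2$mean), 3)
#>    S1    S2
#> 0.018 0.638
contrast_ttest(c2$pairs, c1$pairs, paired = TRUE)$p
#> [1] 1.365413e-05
```

The fold changes show the injected gamma surge (power scales with amplitude
squared), the PAC matrix peaks at the electrode carrying the injected
coupling, and the TPO coherence rises from the estimator's bias floor
(~0.02) to the level set by the shared-source gain, significant under a
paired t test over the three junction pairs.

Running an end-to-end pipeline from a config and summarizing it:

```r
run_pipeline(list(simulate = TRUE, seed = 1,
                  analyses = c("power", "pac", "coherence", "hrv")),
             out_dir = "runs/demo")
pipeline_report("runs/demo")
```

or from a shell: `inst/cli/eegconn run --config cfg.yaml --out runs/demo`.

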