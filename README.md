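# ckc — corticokinematic coherence analysis for MEG

Corticokinematic coherence (CKC) quantifies the phase coupling between limb
kinematics and cortical neurophysiological signals: when a finger is moved
rhythmically (e.g. by a pneumatic actuator at 2–3.5 Hz), proprioceptive
afference drives the contralateral primary sensorimotor cortex at the
movement frequency, and the coherence between MEG channels and the finger's
acceleration peaks there. This package implements the complete analysis
chain for multi-finger stimulation protocols — for MEG methodologists who
want a tested, reproducible reference implementation, and for simulation
studies of the estimator itself.

## What it computes

For MEG epoch DFTs `X_k(f)` and acceleration-reference DFTs `Y_k(f)`
(reference = Euclidean norm of the three accelerometer axes, band-passed
0.5–195 Hz, each 4000-ms epoch normalized to unit norm):

    Pxx(f) = (1/K) Σ_k X_k X_k*      Pyy(f) = (1/K) Σ_k Y_k Y_k*
    Pxy(f) = (1/K) Σ_k X_k Y_k*      Coh(f) = |Pxy|² / (Pxx · Pyy)

The statistic is the maximum coherence at the stimulation frequency over
the gradiometers, tested against the multiple-comparison threshold

    coh_thr = 1 − (α / (N_sens · N_f))^(1 / (N_trials/d − 1)).

Around this core the package provides:

* **Epoching** — 4000-ms epochs, 5-ms overlap, burst-aware segmentation,
  peak-to-peak rejection (2000 fT/cm gradiometers / 4000 fT magnetometers),
  reference normalization, trial-count matching across conditions.
* **Source mapping** — a DICS (dynamic imaging of coherent sources)
  beamformer: single-frequency CSD, rank-2 lead-field reduction,
  diagonally loaded minimum-variance filters, coherence per grid node,
  peak-source extraction.
* **Group statistics** — mean peak-source coordinates, Euclidean
  distances, and a paired sign-flip permutation test (sampled or exact),
  plus tidy contrast tables for external ANOVA tooling.
* **A synthetic-data generator** — stimulus trains for the three condition
  designs (simultaneous constant-frequency, separate, simultaneous
  finger-specific frequencies), three-axis accelerometer traces, a
  single-sphere analytic lead field for a 204 + 102-channel helmet array,
  phase-locked cortical responses with cross-finger interference, 1/f +
  white sensor noise, and artifact transients — so the full pipeline is
  testable without recordings.

## Worked example

A compact single-finger simulation (8 sensor sites, one 300-s burst of
3-Hz stimulation, 500-Hz sampling), fitted and source-localized:

```r
library(ckc)

sim <- ckc_toy_simulation(seed = 3, n_sites = 8, duration_s = 300, gain = 60,
                          grid = cubic_grid(half_extent = 6, spacing = 6),
                          sample_rate = 500)
fit <- ckc(sim$epochs, stim_freq = 3)
fit
#> Corticokinematic coherence fit
#>   K = 75 epochs, stimulation frequency 3 Hz (bin width 0.25 Hz)
#>   peak CKC = 0.876 at channel 10 (planar partner 11: 0.722)
#>   significance threshold (alpha = 0.05, 16 channels) = 0.0750 -> significant

map <- dics_coherence_map(csd_at_frequency(sim$epochs, 3), sim$leadfield)
map
#> DICS coherence map at 3 Hz: 27 nodes, K = 75 epochs
#>   peak coherence 0.792 at node 14 (-40.0, -25.0, 55.0) mm [reg 0.05]
```

Reading the output: 75 accepted 4000-ms epochs gave a peak coherence of
0.876 at the gradiometer nearest the simulated source — far above the
0.075 threshold for a maximum over 16 gradiometers — and the beamformer
places the peak at node 14, which is exactly the node where the generator
planted the source (`sim$node`).

The three-condition experiment (simultaneous constant-frequency vs.
separate vs. simultaneous finger-specific frequencies, plus the summed
separate responses) runs end to end with `run_experiment(ckc_config())`;
`compare_conditions()` then reports per-condition means and the two
directional effects (simultaneous constant > separate; finger-specific
frequencies < separate).

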