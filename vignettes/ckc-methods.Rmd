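---
title: "Corticokinematic coherence: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corticokinematic coherence: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Corticokinematic coherence (CKC) quantifies phase coupling between limb
kinematics and cortical neurophysiological signals. When a finger is moved
rhythmically — here by a pneumatic actuator at 2–3.5 Hz — proprioceptive
afference drives the contralateral primary sensorimotor (SM1) cortex at the
movement frequency, and the magnitude-squared coherence between MEG channels
and the finger's acceleration peaks at that frequency. The package
implements the full analysis chain for multi-finger stimulation protocols:
epoching and artifact rejection, epoch-averaged spectra and coherence, a
multiple-comparison significance threshold, DICS beamformer source mapping
on a volumetric grid, and group-level permutation statistics on peak-source
coordinates. Because no recordings ship with the package, a first-class
synthetic-data generator produces MEG + accelerometer datasets with the
statistical structure the analysis assumes, so every stage is testable.

## Sensor-level estimator

Continuous data are split into epochs of 4000 ms with a 5-ms overlap
(step 3995 ms). For MEG epoch DFTs $X_k(f)$ and acceleration-reference
DFTs $Y_k(f)$, the averaged spectra over the $K$ accepted epochs are

$$P_{xx}(f) = \tfrac1K \sum_k X_k X_k^*, \quad
  P_{yy}(f) = \tfrac1K \sum_k Y_k Y_k^*, \quad
  P_{xy}(f) = \tfrac1K \sum_k X_k Y_k^*,$$

and coherence is $\mathrm{Coh}(f) = |P_{xy}|^2 / (P_{xx} P_{yy}) \in [0,1]$.
The reference is the Euclidean norm of the three accelerometer axes after a
0.5–195 Hz zero-phase band-pass; each reference epoch is normalized to unit
Euclidean norm so all epochs weigh equally in the average. The statistic is
the maximum coherence at the stimulation frequency, searched over the
gradiometers by default (the planar partner of the winning channel is
reported alongside; ties break to the lowest channel index). A raw
rectangular window with DFT length equal to the epoch length is used — the
bare-DFT definition above, with a 0.25-Hz bin width at 4000-ms epochs, which
places the stimulation frequencies 2, 2.5, 3 and 3.5 Hz exactly on bin
centers (asserted at fit time; an off-grid frequency is an error unless
snapping is requested explicitly).

Significance of the peak over $N_{sens}$ channels and $N_f$ frequencies of
interest is assessed against

$$\mathrm{coh}_{thr} = 1 - \left(\frac{\alpha}{N_{sens} N_f}\right)^{1/(N_{trials}/d - 1)}.$$

Two knobs deserve comment. First, $\alpha$ is exposed rather than fixed at
0.05. Second, the trial-overlap divisor $d$ defaults to 1 (no correction):
the conventional description of $d$ mixes a count with a duration (an
"overlap of 5 ms" used as a divisor of a trial count), and no reading we
tried reproduces consistent trial arithmetic, so the formula is applied
verbatim with $d$ as an explicit argument and no hidden correction. For the
same reason the 3995-ms step is a configuration default, not a hard-coded
constant.

Epoch hygiene: epochs are half-open `[start, start + 4000 ms)` in samples,
laid out independently inside each stimulation burst (an epoch must lie
entirely within one burst); an epoch is dropped iff any gradiometer exceeds
2000 fT/cm or any magnetometer 4000 fT peak-to-peak — *strictly* greater,
so at-threshold epochs are kept. Rejection is monotone in the thresholds
and commutes with channel reordering; both properties are tested.

## Source-level estimator

The DICS (dynamic imaging of coherent sources) stage estimates coherence
between the reference and every node of a volumetric grid (3-mm spacing by
default). At the stimulation bin the sensor CSD
$C = \tfrac1K \sum_k x_k x_k^H$, the sensor–reference cross-spectral vector
and the reference power are computed from the same epochs. Each node's
3-column lead-field block is reduced to the two columns spanning the top-2
singular directions (the quasi-radial third direction of a sphere model is
silent), with a deterministic sign convention. The spatial filter is the
unit-gain minimum-variance beamformer on the diagonally loaded CSD,
$W = (L^H C^{-1} L)^{-1} L^H C^{-1}$, and the node's coherence is maximized
over orientation within the reduced 2-D space, which has the closed form
$\mathrm{coh} = \Re(b^H M^{-1} b)/P_{yy}$ with $M = L^H C^{-1} L$ and
$b = L^H C^{-1} P_{xy}$. No DICS variant is canonical in the literature we
follow; this standard construction with loading
$\lambda = 0.05 \cdot \mathrm{mean}(\mathrm{diag}\,C)$ (exposed as `reg`)
was chosen because the same-data CSD doubles as the noise model, mirroring
noise-covariance-from-the-same-file practice. The source stage defaults to
gradiometers only, so no cross-unit whitening is needed; magnetometers can
be included by passing an explicit channel set, at the user's own whitening
responsibility.

Two properties of sample-CSD beamformers matter for interpreting maps.
(i) The filter needs $K$ comfortably above the channel count; with
$K \lesssim N_{chan}$ the CSD is rank-deficient and both localization and
the coherence level degrade. (ii) Even above that rank limit the beamformed
coherence is biased downward by a factor of roughly $(K - N_{chan})/K$.
The package's validation suites therefore use reduced sensor arrays with
$K \gg N_{chan}$ (e.g. 16 gradiometers at 75 epochs) when checking
point-source recovery and sensor–source consistency.

## Group statistics

Peak-source coordinates (one triple per subject × finger × condition, in an
MNI-like frame supplied by the user or the simulator) are compared with a
permutation test: the observed statistic is the Euclidean distance between
the two group-mean coordinates, and the null swaps each subject's pair of
coordinates independently with probability ½. The paired (sign-flip) null
was chosen over pooled relabeling because the design is repeated-measures;
pooled relabeling remains available via `method = "pooled"`, and an exact
mode enumerates all $2^n$ swap patterns. p-values use the add-one rule
$(b+1)/(m+1)$ with a $\geq$ tail, which avoids $p = 0$ and is conservative.
An alternative statistic — the mean of per-subject distances rather than
the distance of means — is deliberately *not* the default: the distance
between group means is the quantity whose null the sign-flip scheme
permutes exactly. Repeated-measures ANOVA, post-hoc and normality testing
are out of scope; `condition_contrast_table()` emits the tidy long-format
table those tools consume.

## The synthetic-data generator

The generator emulates the three experimental conditions of a four-finger
proprioceptive protocol: all fingers at a common 3 Hz in three 1-min bursts
(`simultaneous_constant`), one finger at a time at 3 Hz
(`separate`), and continuous 4-min stimulation at finger-specific
frequencies 2/2.5/3/3.5 Hz (`simultaneous_varied`). Onsets are strictly
periodic within bursts and quantized to the sample grid per onset (so a
3-Hz train has a 333-ms onset asynchrony at 1 kHz and the long-run rate
stays exactly 3 Hz).

**Waveforms.** The actuator pulse and the cortical evoked response are not
specified by any source we treat as authoritative, and coherence is
phase-locking–based, so any fixed kernel serves. Defaults: the
accelerometer sees the second derivative of an 80-ms Hann displacement
pulse per onset (a physically shaped, zero-mean acceleration transient
whose magnitude keeps its dominant spectral line at the stimulation
frequency), and the cortex responds with a 60-ms biphasic pulse. Both are
explicit configuration, not claims about physiology.

**Forward model.** A single-sphere analytic field model (the closed-form
field of a current dipole in a conducting sphere) maps sources to a
helmet-like array of 102 sites × (2 planar gradiometers + 1 magnetometer).
Realistic BEM forward modeling from MRI is out of scope by design — the
sphere model reproduces the properties the pipeline relies on (distance
decay, radial silence, 3-component lead fields of effective rank 2).

**Noise.** Sensor noise is specified as amplitude spectral densities
(fT/cm/√Hz at gradiometers): white noise at 2 and a 1/f background at 4
(referenced to 1 Hz), magnetometers at twice those. Densities — rather
than per-sample SDs — make the per-bin SNR, and therefore coherence,
invariant to the simulation sampling rate, so reduced-rate validation runs
live in the same coherence regime as 1-kHz runs.

**Coupling strength.** The default source gain (12) was set once so that
the single-finger (separate) condition lands near the mid-0.4s to mid-0.5s
sensor CKC range typical of healthy adults in this paradigm; with it,
simultaneous constant-frequency stimulation saturates higher and varied
frequencies lower, as expected.

**Cross-finger interference.** The generator encodes the additive-afference
account of multi-finger stimulation: concurrently stimulated fingers
project into partly shared cortical circuitry, which *sums* coherent input
(strengthening CKC when all fingers move at one frequency) and *distracts*
finger-specific phase locking when frequencies differ. Mechanism: each
cortical response onset for finger $f$ is delayed by
$c \cdot s \cdot \bar z_{-f}(t)$, where $\bar z_{-f}$ is the standardized
sum of the *other* fingers' drive waveforms, $c$ is the interference
weight (default 0.6) and $s = 60$ ms the latency scale. When the other
fingers share $f$'s frequency this delay is the same at every onset — a
harmless constant phase offset; at different frequencies it varies
quasi-randomly from onset to onset and erodes coherence. The latency scale
was chosen so the varied-frequency condition loses roughly the
one-to-two-tenths of coherence seen empirically in this paradigm; it is a
generator parameter, not a measured quantity. Baseline onset jitter is
2 ms, per-onset amplitude CV 0.1.

**Artifacts and randomness.** Optional square transients of 3000 fT/cm
(between the gradiometer threshold and the magnetometer threshold's scale)
exercise rejection. One root seed spawns deterministic child seeds per
stream (sensor noise, jitter, artifacts, per-run), so toggling one
component never shifts another stream's draws, and identical configuration
plus seed reproduces recordings bit for bit.

**What the generator does not emulate** — and hence what green tests do
*not* establish about real data: head movement, cardiac/ocular artifacts
and their removal, environmental interference structure (tSSS/OTP are out
of scope), between-subject anatomical variability, BEM-accurate field
patterns, and any nonlinearity of cortical summation. Conclusions from the
synthetic experiments are about the *estimators*, not about physiology.

## Numerical choices and degenerate inputs

* Rectangular window, DFT length = epoch length: matches the bare-DFT
  spectral definitions; no taper is applied anywhere.
* Zero-phase (forward–backward) filtering for the acceleration band-pass,
  realized as a high-pass/low-pass Butterworth cascade (orders 2 and 5 per
  pass) — a direct wide-band band-pass design is numerically
  ill-conditioned at a 0.5–195 Hz band. Pass-band flat within 1%, >20 dB
  down at 250 Hz, DC removed exactly.
* Zero-power bins yield `NA` coherence (undefined), never 0.
* Exact peak ties resolve to the lowest channel/node index.
* The CSD is symmetrized to exact Hermitian form before inversion; a
  singular CSD at zero loading is an error that names the remedy.
* Epoch-shuffling surrogates are *not* used to null the coherence: with a
  3995-ms step, a 3-Hz stimulus phase advances only ~5.4° per epoch, so
  re-paired epochs remain nearly phase-aligned and coherence survives
  shuffling — a genuine property of periodic-stimulus CKC at this epoch
  grid, not an implementation artifact. The surrogate that does destroy
  phase locking, and the one the validation suite uses, applies a random
  circular time shift to each reference epoch.

## Problem sizes used in validation

The validation suites run reduced-scale simulations chosen to keep each
property's discriminating power: reduced arrays of 8–16 sites, 500-Hz
sampling (noise densities make this coherence-neutral, see above), one to
three 60-s bursts ($K = 15$–45 epochs) for sensor-level properties, a
≤500-node 3-mm grid with 16 gradiometers and $K = 75$ for beamformer
recovery, and 20-seed Monte-Carlo loops for directional effects. The
full-scale defaults (102 sites, 1 kHz, three 1-min bursts per condition,
4-min varied run, 3-mm grid) remain the generator's reference
configuration.

## Known limitations

* The sensor-level peak statistic reports the maximum gradiometer; the
  vector-sum convention for a planar pair is exposed via the partner
  channel's coherence but is not the default statistic.
* Beamformed coherence inherits the $(K - N_{chan})/K$ downward bias of
  sample-CSD minimum-variance filters; maps are comparable within a
  configuration, not across channel counts.
* The interference mechanism is one concrete realization of "other fingers
  disturb phase locking"; it reproduces directions and plausible effect
  sizes, not a fitted physiological model.
* Harmonics of the stimulation frequency are simulated but not analyzed;
  the statistics address the fundamental only.
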