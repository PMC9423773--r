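Package: ckc
Title: Corticokinematic Coherence Analysis for MEG and Accelerometer Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for corticokinematic coherence (CKC) analysis of
    magnetoencephalography (MEG) recordings during rhythmic proprioceptive
    stimulation of the fingers. Implements epoch-averaged auto- and
    cross-spectra, magnitude-squared coherence between MEG channels and the
    Euclidean norm of three-axis finger acceleration, a multiple-comparison
    significance threshold for the peak coherence, a DICS (dynamic imaging of
    coherent sources) beamformer for source-space coherence maps on a
    volumetric grid, and permutation tests on 3-D peak-source coordinates.
    Includes a synthetic-data generator (stimulus trains, accelerometer
    traces, a single-sphere analytic lead field, phase-locked cortical
    responses with cross-finger interference, 1/f plus white sensor noise and
    artifact transients) so the full pipeline can be exercised and validated
    without access to real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
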