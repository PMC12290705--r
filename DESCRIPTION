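Package: pcdenoise
Title: Phase-Coupling Decomposition for Speech-Artifact Removal in
    Intracranial Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised data-driven spatial filtering to identify and remove
    acoustic-induced (speech-vibration) artifacts from multichannel
    intracranial electrophysiological recordings. Implements the
    phase-coupling decomposition pipeline: speech-artifact frequency band
    estimation from the produced audio, spatiospectral decomposition (a
    generalized eigenvalue problem maximizing narrow-band versus
    surrounding-band power), phase-coupling optimization of the mean vector
    length between projected analytic signals and the audio, and low-rank
    artifact rejection. Ships a synthetic-data generator with known ground
    truth (speech-locked gamma sources plus a controllable audio-like
    artifact), baseline denoisers (common average reference, PCA+ICA), and
    evaluation metrics (coherence, phase-locking value, intertrial phase
    consistency, PCA-loading cosine similarity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
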