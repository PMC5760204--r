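Package: ipnblink
Title: Spike-Train and Eyelid Analysis for Cerebellar Nuclear Recordings
    During Eyeblink Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trial-aligned extracellular recordings of
    cerebellar interpositus nucleus (IpN) neurons during delay eyeblink
    conditioning. Provides eyelid-trace normalization, smoothing and
    quality filtering with conditioned-response (CR) detection; spike
    density function estimation and baseline statistics; classification of
    CS-US spike facilitation and suppression and of transient CS/US
    responses; trial-by-trial spike-behavior correlation machinery
    (correlation matrices, temporal cross-correlation, bootstrap
    population tests, pooled slopes, and exact power analysis for
    correlation tests); a surrogate simple-spike expansion based on
    per-millisecond inter-spike-interval statistics driving a convergent
    inhibitory integrate-and-fire model of nuclear neurons; and a
    synthetic-data generator with known ground truth for validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    metafor
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
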