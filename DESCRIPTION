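Package: spikeosc
Title: Spiking Speech Networks and Neural Oscillation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and training physiologically inspired
    spiking neural networks on speech-like audio, and for analyzing the
    neural oscillations they produce. Implements adaptive leaky
    integrate-and-fire (AdLIF) neuron dynamics trained end-to-end with a
    boxcar surrogate gradient inside a waveform-to-symbol pipeline (Mel
    filterbank frontend, auditory convolution, LIF nerve fibers,
    recurrent spiking layers, CTC loss and greedy decoding), with
    optional Dale's-law sign constraints and firing-rate regularization.
    An oscillation-analysis toolkit builds EEG-like population signals
    from spike rasters, decomposes them into canonical frequency bands,
    and quantifies phase-amplitude coupling with the modulation index
    and mean vector length metrics against cut-and-swap surrogate nulls.
    Synthetic generators provide coupled-oscillation signals with known
    ground truth, Poisson spike rasters, tone-sequence corpora and noise
    inputs so the full stack can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
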