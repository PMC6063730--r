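Package: statephys
Title: State-Dependent Membrane Potential and Unitary EPSP Analysis for
    Awake Cortical Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for intracellular recordings from awake-mouse
    cortex: segmentation of recordings into behavioral and cortical states
    from whisker motion and 1-5 Hz local field potential (LFP) power,
    state-resolved membrane potential statistics (mean, SD, firing rate, FFT
    amplitude spectra, Vm-LFP cross-correlation), quantification of
    optogenetically evoked unitary excitatory postsynaptic potentials
    (triggered averages, amplitude, onset latency, rise time), and exact
    nonparametric Wilcoxon tests by full enumeration. Includes a synthetic
    session generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
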