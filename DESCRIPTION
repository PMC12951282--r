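Package: meaflow
Title: Spike Timing, Level Sensing and Environment Control for Incubated
    Microelectrode Arrays
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for microelectrode-array (MEA) electrophysiology under
    closed-loop environmental control. Implements the extracellular
    signal-conditioning and threshold spike-detection chain (Butterworth
    high-pass, Savitzky-Golay smoothing, smoothed nonlinear energy operator,
    MAD thresholds), spike-time-triggered raster plots (STTRP) with band
    latency, transmission fidelity, cosine pattern-similarity and
    Mann-Kendall/Fisher trend statistics, a subpixel laser-reflection
    liquid-level sensor model, deterministic simulators of the volume,
    perfusion-concentration and temperature control loops of an MEA
    incubator, and a ground-truthed synthetic recording generator so the
    whole analysis chain is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'io.R'
    'cli.R'
    'envsim.R'
    'ephys-filter.R'
    'ephys-detect.R'
    'inkulevel.R'
    'similarity.R'
    'sttrp.R'
    'synth.R'
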