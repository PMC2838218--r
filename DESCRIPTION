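Package: meaSpike
Title: Adaptive Spike Detection and PCA-Hierarchical Sorting for
    Microelectrode Array Recordings
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Unsupervised amplitude-threshold spike detection and waveform
    classification for extracellular multi-electrode array (MEA) recordings.
    Provides five adaptive noise-level estimators operating on 10 ms windows
    (fixed and adaptive RMS-percentile thresholds, a clean-window voltage
    percentile smoother, and window-extrema smoothers), bipolar threshold
    crossing with a +/-1 ms peak validation rule, peak-aligned 2 ms waveform
    extraction, PCA projection with hierarchical clustering cut by a
    dispersion-versus-centroid-distance criterion, cluster pruning and
    noise-cluster flagging, signal reconstruction from cluster mean
    waveforms, and screening-test evaluation (sensitivity, specificity,
    PPV, NPV) against ground truth. Includes a seedable simulator of
    ground-truthed MEA recordings (triangular and overlapped-complex action
    potentials in band-limited Gaussian noise at a target SNR) so the whole
    pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'detection.R'
    'estimators.R'
    'evaluation.R'
    'io.R'
    'meaSpike-package.R'
    'methods-show.R'
    'pipeline.R'
    'preprocess.R'
    'sorting.R'
    'synthetic.R'
    'utils.R'
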