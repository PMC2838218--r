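#' @include AllClasses.R
NULL

#' Accessors for meaSpike objects
#'
#' \code{samples()} returns the voltage vector of a [Recording];
#' \code{samplingRate()} its sampling rate in Hz; \code{nSamples()} and
#' \code{duration()} its length in samples and seconds;
#' \code{groundTruth()} the event table of a [SimulatedRecording];
#' \code{events()} the event table of a [SpikeEvents] or [WaveformSet];
#' \code{waveforms()} the snippet matrix of a [WaveformSet];
#' \code{clusterLabels()} the per-waveform labels of a [SpikeSorting].
#'
#' @param x the object.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases samples samplingRate nSamples duration groundTruth events
#'   waveforms clusterLabels
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname accessors
#' @export
setGeneric("waveforms", function(x) standardGeneric("waveforms"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname bandpassFilter
#' @export
setGeneric("bandpassFilter",
    function(x, lowHz = 150, highHz = 2500, order = 2, zeroPhase = FALSE)
        standardGeneric("bandpassFilter"))

#' @rdname estimateThresholds
#' @export
setGeneric("estimateThresholds",
    function(x, method = c("adabandflt", "bandflt", "limada", "adaflt",
        "adaflt128"), ...)
        standardGeneric("estimateThresholds"))

#' @rdname detectSpikes
#' @export
setGeneric("detectSpikes",
    function(x, thresholds, validate = TRUE, ...)
        standardGeneric("detectSpikes"))

#' @rdname extractWaveforms
#' @export
setGeneric("extractWaveforms",
    function(x, events, windowMs = 2, ...) standardGeneric("extractWaveforms"))

#' @rdname sortSpikes
#' @export
setGeneric("sortSpikes",
    function(x, ...) standardGeneric("sortSpikes"))

#' @rdname reconstructSignal
#' @export
setGeneric("reconstructSignal",
    function(x, sorting, traceLen, ...) standardGeneric("reconstructSignal"))
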