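#' @include AllGenerics.R
NULL

#' Construct a Recording
#'
#' @param samples numeric voltage trace in microvolts.
#' @param fsHz sampling rate in Hz.
#' @param channelId electrode label.
#' @param t0Sec time of the first sample in seconds.
#' @return a [Recording-class] object.
#' @examples
#' rec <- Recording(rnorm(250), fsHz = 25000)
#' samplingRate(rec)
#' @export
Recording <- function(samples, fsHz, channelId = "ch1", t0Sec = 0) {
    new("Recording", samples = as.numeric(samples), fsHz = fsHz,
        channelId = channelId, t0Sec = t0Sec)
}

#' @rdname accessors
setMethod("samples", "Recording", function(x) x@samples)

#' @rdname accessors
setMethod("samplingRate", "Recording", function(x) x@fsHz)

#' @rdname accessors
setMethod("samplingRate", "ThresholdTrace", function(x) x@fsHz)

#' @rdname accessors
setMethod("samplingRate", "WaveformSet", function(x) x@fsHz)

#' @rdname accessors
setMethod("nSamples", "Recording", function(x) length(x@samples))

#' @rdname accessors
setMethod("duration", "Recording", function(x) length(x@samples) / x@fsHz)

#' @rdname accessors
setMethod("groundTruth", "SimulatedRecording", function(x) x@groundTruth)

#' @rdname accessors
setMethod("events", "SpikeEvents", function(x) x@events)

#' @rdname accessors
setMethod("events", "WaveformSet", function(x) x@events)

#' @rdname accessors
setMethod("waveforms", "WaveformSet", function(x) x@waveforms)

#' @rdname accessors
setMethod("clusterLabels", "SpikeSorting", function(x) x@labels)

setMethod("show", "Recording", function(object) {
    cat(sprintf("%s on channel '%s': %d samples at %g Hz (%.3f s)\n",
        class(object), object@channelId, length(object@samples),
        object@fsHz, length(object@samples) / object@fsHz))
    if (is(object, "SimulatedRecording")) {
        cat(sprintf("  ground truth: %d events, %d classes; SNR %.3g dB\n",
            nrow(object@groundTruth),
            length(unique(object@groundTruth$class_id)),
            object@config$snr_db))
    }
    invisible(NULL)
})

setMethod("show", "ThresholdTrace", function(object) {
    nv <- sum(object@valid)
    cat(sprintf(
        "ThresholdTrace [%s]: %d windows of %d samples, %d valid\n",
        object@method, length(object@pos), object@windowLen, nv))
    if (nv > 0) {
        i <- max(which(object@valid))
        cat(sprintf("  last thresholds: +%.3f / %.3f uV (multiplier %g)\n",
            object@pos[i], object@neg[i], object@multiplier))
    }
    invisible(NULL)
})

setMethod("show", "SpikeEvents", function(object) {
    ev <- object@events
    cat(sprintf(
        "SpikeEvents: %d events (%d '+', %d '-'), %d validated; %d dropped at boundary\n",
        nrow(ev), sum(ev$polarity == "+"), sum(ev$polarity == "-"),
        sum(ev$validated), object@nDroppedBoundary))
    invisible(NULL)
})

setMethod("show", "WaveformSet", function(object) {
    cat(sprintf(
        "WaveformSet: %d waveforms x %d samples, peak aligned at column %d (%d dropped)\n",
        nrow(object@waveforms), ncol(object@waveforms),
        object@alignmentOffset, object@nDropped))
    invisible(NULL)
})

setMethod("show", "SpikeSorting", function(object) {
    cat(sprintf("SpikeSorting: %d clusters over %d waveforms\n",
        object@k, length(object@labels)))
    cat(sprintf("  sizes: %s\n", paste(object@sizes, collapse = ", ")))
    cat(sprintf("  accepted: %d; noise-flagged: %d; singletons: %d\n",
        sum(object@accepted), sum(object@isNoise), sum(object@sizes == 1L)))
    invisible(NULL)
})

setMethod("show", "ScreeningResult", function(object) {
    cat(sprintf("ScreeningResult: TP=%d FP=%d TN=%d FN=%d\n",
        object@TP, object@FP, object@TN, object@FN))
    fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
    cat(sprintf("  Se=%s Sp=%s PPV=%s NPV=%s\n", fmt(object@Se),
        fmt(object@Sp), fmt(object@PPV), fmt(object@NPV)))
    for (n in object@notes) cat("  note:", n, "\n")
    invisible(NULL)
})
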