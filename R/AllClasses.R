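#' @import methods
NULL

#' Recording: a sampled extracellular voltage trace
#'
#' The universal input container: a single-channel voltage trace in
#' microvolts with its sampling rate. All downstream operations
#' (filtering, threshold estimation, detection) consume a
#' \code{Recording}.
#'
#' @slot samples numeric vector of voltages (microvolts).
#' @slot fsHz sampling rate in Hz.
#' @slot channelId character label of the source electrode.
#' @slot t0Sec time of the first sample, in seconds.
#'
#' @seealso [Recording()] for the constructor, [simulateRecording()] for
#'   simulated inputs.
#' @exportClass Recording
setClass("Recording",
    representation(
        samples = "numeric",
        fsHz = "numeric",
        channelId = "character",
        t0Sec = "numeric"
    ),
    prototype(channelId = "ch1", t0Sec = 0)
)

setValidity("Recording", function(object) {
    msg <- NULL
    if (length(object@fsHz) != 1L || !is.finite(object@fsHz) ||
        object@fsHz <= 0) {
        msg <- c(msg, "fsHz must be a single positive finite number")
    }
    if (anyNA(object@samples) || any(!is.finite(object@samples))) {
        msg <- c(msg, "samples must be finite")
    }
    if (length(object@t0Sec) != 1L || !is.finite(object@t0Sec)) {
        msg <- c(msg, "t0Sec must be a single finite number")
    }
    if (is.null(msg)) TRUE else msg
})

#' SimulatedRecording: a Recording with ground truth attached
#'
#' Produced by [simulateRecording()]. In addition to the mixed trace it
#' retains the clean (noise-free) signal, the scaled noise component and
#' the ground-truth event table, so detector and sorter output can be
#' scored against known events.
#'
#' @slot clean numeric, the noise-free spike train (microvolts).
#' @slot noiseComponent numeric, the scaled additive noise (microvolts).
#' @slot groundTruth data.frame with columns \code{event_index} (1-based
#'   sample index of the event's tallest peak), \code{time_s},
#'   \code{class_id} and \code{peak_amplitude_uv}.
#' @slot config list, the resolved simulation configuration.
#'
#' @exportClass SimulatedRecording
setClass("SimulatedRecording",
    contains = "Recording",
    representation(
        clean = "numeric",
        noiseComponent = "numeric",
        groundTruth = "data.frame",
        config = "list"
    )
)

setValidity("SimulatedRecording", function(object) {
    msg <- NULL
    n <- length(object@samples)
    if (length(object@clean) != n || length(object@noiseComponent) != n) {
        msg <- c(msg, "clean and noiseComponent must match samples length")
    }
    gt <- object@groundTruth
    need <- c("event_index", "time_s", "class_id", "peak_amplitude_uv")
    if (!all(need %in% names(gt))) {
        msg <- c(msg, paste("groundTruth must have columns:",
            paste(need, collapse = ", ")))
    } else if (nrow(gt) > 1 && is.unsorted(gt$event_index)) {
        msg <- c(msg, "groundTruth must be sorted by event_index")
    }
    if (is.null(msg)) TRUE else msg
})

#' ThresholdTrace: per-window detection thresholds
#'
#' The output of a noise-level estimator run over a full trace: one
#' positive and one negative threshold per 10 ms window, with a validity
#' flag that is FALSE until the estimator's initialization completed.
#'
#' @slot pos numeric, positive threshold per window (microvolts).
#' @slot neg numeric, negative threshold per window (microvolts).
#' @slot valid logical, whether the estimator was initialized at that window.
#' @slot windowLen integer, samples per window.
#' @slot fsHz sampling rate in Hz.
#' @slot method character, estimator name.
#' @slot multiplier numeric, the threshold multiple of the noise estimate.
#'
#' @exportClass ThresholdTrace
setClass("ThresholdTrace",
    representation(
        pos = "numeric",
        neg = "numeric",
        valid = "logical",
        windowLen = "integer",
        fsHz = "numeric",
        method = "character",
        multiplier = "numeric"
    )
)

setValidity("ThresholdTrace", function(object) {
    msg <- NULL
    n <- length(object@pos)
    if (length(object@neg) != n || length(object@valid) != n) {
        msg <- c(msg, "pos, neg and valid must have equal length")
    }
    v <- object@valid & !is.na(object@pos) & !is.na(object@neg)
    if (any(object@pos[v] < object@neg[v])) {
        msg <- c(msg, "valid windows must satisfy pos >= neg")
    }
    if (length(object@windowLen) != 1L || object@windowLen < 1L) {
        msg <- c(msg, "windowLen must be a single positive integer")
    }
    if (is.null(msg)) TRUE else msg
})

#' SpikeEvents: detected (and optionally validated) spike time stamps
#'
#' @slot events data.frame with columns \code{peak_index} (1-based sample
#'   index of the excursion extremum), \code{time_s}, \code{polarity}
#'   ("+" or "-"), \code{peak_amplitude_uv} (signed, from the filtered
#'   trace) and \code{validated}.
#' @slot fsHz sampling rate in Hz.
#' @slot nDroppedBoundary integer, candidates discarded because the
#'   validation window extended past the trace boundary.
#'
#' @exportClass SpikeEvents
setClass("SpikeEvents",
    representation(
        events = "data.frame",
        fsHz = "numeric",
        nDroppedBoundary = "integer"
    ),
    prototype(nDroppedBoundary = 0L)
)

setValidity("SpikeEvents", function(object) {
    need <- c("peak_index", "time_s", "polarity", "peak_amplitude_uv",
        "validated")
    if (!all(need %in% names(object@events))) {
        return(paste("events must have columns:", paste(need, collapse = ", ")))
    }
    pol <- object@events$polarity
    if (length(pol) && !all(pol %in% c("+", "-"))) {
        return("polarity must be '+' or '-'")
    }
    TRUE
})

#' WaveformSet: peak-aligned spike snippets
#'
#' An N x c matrix of extracted waveforms (N spikes, c samples; c = 50
#' for a 2 ms window at 25 kHz), each row aligned so its tallest peak
#' (largest absolute value) sits at \code{alignmentOffset}.
#'
#' @slot waveforms numeric matrix, N x c, microvolts.
#' @slot alignmentOffset integer, 1-based column index of the aligned peak.
#' @slot fsHz sampling rate in Hz.
#' @slot events data.frame, the originating events (one row per waveform).
#' @slot nDropped integer, events dropped at trace boundaries.
#'
#' @exportClass WaveformSet
setClass("WaveformSet",
    representation(
        waveforms = "matrix",
        alignmentOffset = "integer",
        fsHz = "numeric",
        events = "data.frame",
        nDropped = "integer"
    ),
    prototype(nDropped = 0L)
)

setValidity("WaveformSet", function(object) {
    msg <- NULL
    if (nrow(object@waveforms) != nrow(object@events)) {
        msg <- c(msg, "one event row per waveform row required")
    }
    off <- object@alignmentOffset
    if (length(off) != 1L || off < 1L || off > max(1L, ncol(object@waveforms))) {
        msg <- c(msg, "alignmentOffset must lie within the waveform columns")
    }
    if (is.null(msg)) TRUE else msg
})

#' SpikeSorting: hierarchical classification of a WaveformSet
#'
#' The chosen partition of the PCA scores, with per-cluster centroids,
#' dispersions, sizes, acceptance (minimum-size pruning) and noise flags
#' (mean-waveform peak-to-peak below the noise amplitude floor).
#'
#' @slot labels integer cluster label per waveform (1..k).
#' @slot k integer, number of clusters in the chosen partition.
#' @slot centroids numeric matrix, k x 2 cluster centres in PC space.
#' @slot dispersions numeric, per-cluster radius (maximum member-to-
#'   centroid distance), the dispersion compared against centroid
#'   distances when choosing the partition.
#' @slot sizes integer, per-cluster member counts.
#' @slot accepted logical, clusters meeting the minimum size.
#' @slot isNoise logical, accepted clusters whose mean waveform
#'   peak-to-peak amplitude is below the noise floor.
#' @slot clusterMeans numeric matrix, k x c mean waveform per cluster.
#' @slot scores numeric matrix, N x 2 PCA projections.
#' @slot pca list with \code{rotation}, \code{center}, \code{sdev}.
#' @slot tree the agglomerative merge tree (an \code{hclust} object), or
#'   NULL for N = 1.
#' @slot config list, the resolved sorting configuration.
#'
#' @exportClass SpikeSorting
setClass("SpikeSorting",
    representation(
        labels = "integer",
        k = "integer",
        centroids = "matrix",
        dispersions = "numeric",
        sizes = "integer",
        accepted = "logical",
        isNoise = "logical",
        clusterMeans = "matrix",
        scores = "matrix",
        pca = "list",
        tree = "ANY",
        config = "list"
    )
)

setValidity("SpikeSorting", function(object) {
    msg <- NULL
    k <- object@k
    if (length(object@sizes) != k || length(object@dispersions) != k ||
        length(object@accepted) != k || length(object@isNoise) != k) {
        msg <- c(msg, "per-cluster slots must have length k")
    }
    if (length(object@labels) &&
        (min(object@labels) < 1L || max(object@labels) > k)) {
        msg <- c(msg, "labels must lie in 1..k")
    }
    if (sum(object@sizes) != length(object@labels)) {
        msg <- c(msg, "cluster sizes must sum to the number of waveforms")
    }
    if (is.null(msg)) TRUE else msg
})

#' ScreeningResult: confusion counts and screening-test statistics
#'
#' True/false positive and negative counts from matching detections to
#' ground truth, with sensitivity Se = TP/(TP+FN), specificity
#' Sp = TN/(TN+FP), positive predictive value PPV = TP/(TP+FP) and
#' negative predictive value NPV = TN/(TN+FN). A ratio whose denominator
#' is zero is NA and its reason is recorded in \code{notes}.
#'
#' @slot TP,FP,TN,FN integer counts.
#' @slot Se,Sp,PPV,NPV numeric in [0, 1], or NA when undefined.
#' @slot notes character, reasons for undefined ratios.
#'
#' @exportClass ScreeningResult
setClass("ScreeningResult",
    representation(
        TP = "integer", FP = "integer", TN = "integer", FN = "integer",
        Se = "numeric", Sp = "numeric", PPV = "numeric", NPV = "numeric",
        notes = "character"
    ),
    prototype(notes = character())
)

setValidity("ScreeningResult", function(object) {
    counts <- c(object@TP, object@FP, object@TN, object@FN)
    if (any(counts < 0L)) return("counts must be non-negative")
    ratios <- c(object@Se, object@Sp, object@PPV, object@NPV)
    ok <- !is.na(ratios)
    if (any(ratios[ok] < 0 | ratios[ok] > 1)) {
        return("defined ratios must lie in [0, 1]")
    }
    TRUE
})
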