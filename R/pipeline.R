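## End-to-end orchestration: simulate (or load) -> filter -> thresholds
## -> detect -> validate -> extract -> sort -> evaluate, with a JSON-able
## run report and reproducibility metadata.

#' Pipeline configuration
#'
#' @param simulation a list from [simulationConfig()], or NULL to run on
#'   a provided recording.
#' @param method noise estimator (see [noiseEstimator()]).
#' @param multiplier threshold multiplier, or NULL for the method
#'   default.
#' @param lowHz,highHz,order band-pass filter settings.
#' @param validate apply the peak-validation rule before extraction.
#' @param extractionWindowMs waveform window in milliseconds.
#' @param sorting a list from [sortingConfig()].
#' @param toleranceMs ground-truth matching tolerance in milliseconds.
#' @param screenValidated score validated (TRUE) or raw (FALSE)
#'   detections against the ground truth.
#' @param seed integer seed for the simulation.
#' @return configuration list.
#' @export
pipelineConfig <- function(simulation = simulationConfig(),
        method = "adabandflt", multiplier = NULL, lowHz = 150,
        highHz = 2500, order = 2, validate = TRUE,
        extractionWindowMs = 2, sorting = sortingConfig(),
        toleranceMs = 1, screenValidated = FALSE, seed = NULL) {
    if (!method %in% estimatorMethods) {
        stop("pipelineConfig: unknown estimator '", method, "'; use one of ",
            paste(estimatorMethods, collapse = ", "))
    }
    list(simulation = simulation, method = method, multiplier = multiplier,
        low_hz = lowHz, high_hz = highHz, order = order,
        validate = validate, extraction_window_ms = extractionWindowMs,
        sorting = sorting, tolerance_ms = toleranceMs,
        screen_validated = screenValidated, seed = seed)
}

#' Run the full pipeline
#'
#' Stage order: detection (filter, thresholds, crossings, validation),
#' PCA feature extraction, hierarchical classification; when ground
#' truth is available a screening evaluation is appended. Returns all
#' per-stage objects plus a plain-list run report.
#'
#' @param config a list from [pipelineConfig()].
#' @param recording an input [Recording-class]; if NULL, a
#'   [SimulatedRecording-class] is generated from
#'   \code{config$simulation}.
#' @param verbose print per-stage counts.
#' @return list with \code{recording}, \code{filtered},
#'   \code{thresholds}, \code{spikes}, \code{waveforms}, \code{sorting},
#'   \code{screening} (NULL without ground truth),
#'   \code{reconstruction} and \code{report}.
#' @examples
#' \dontrun{
#' run <- runPipeline(pipelineConfig(seed = 1))
#' run$report$sorting$n_clusters
#' }
#' @export
runPipeline <- function(config = pipelineConfig(), recording = NULL,
        verbose = FALSE) {
    say <- function(...) if (verbose) message(sprintf(...))
    if (is.null(recording)) {
        if (is.null(config$simulation)) {
            stop("runPipeline: no recording given and simulation disabled")
        }
        recording <- simulateRecording(config$simulation, seed = config$seed)
        say("simulated %d samples, %d ground-truth events",
            nSamples(recording), nrow(groundTruth(recording)))
    }
    truth <- if (is(recording, "SimulatedRecording"))
        groundTruth(recording) else NULL

    filtered <- bandpassFilter(recording, config$low_hz, config$high_hz,
        config$order)
    thArgs <- list(x = filtered, method = config$method)
    if (!is.null(config$multiplier)) thArgs$multiplier <- config$multiplier
    thresholds <- do.call(estimateThresholds, thArgs)
    say("thresholds [%s]: %d windows, %d valid", config$method,
        length(thresholds@pos), sum(thresholds@valid))

    spikes <- detectSpikes(filtered, thresholds, validate = config$validate)
    ev <- events(spikes)
    say("detected %d candidates, %d validated, %d dropped at boundary",
        nrow(ev), sum(ev$validated), spikes@nDroppedBoundary)

    wfs <- extractWaveforms(filtered, spikes,
        windowMs = config$extraction_window_ms,
        validatedOnly = config$validate)
    say("extracted %d waveforms x %d samples (%d dropped)",
        nrow(waveforms(wfs)), ncol(waveforms(wfs)), wfs@nDropped)

    sorting <- NULL
    reconstruction <- NULL
    if (nrow(waveforms(wfs)) >= 2L) {
        sorting <- sortSpikes(wfs, config$sorting)
        reconstruction <- reconstructSignal(wfs, sorting,
            nSamples(recording))
        say("sorting: %d clusters (sizes %s), %d accepted, %d noise",
            sorting@k, paste(sorting@sizes, collapse = "/"),
            sum(sorting@accepted), sum(sorting@isNoise))
    }

    screening <- NULL
    if (!is.null(truth)) {
        evScreen <- if (config$screen_validated)
            ev[ev$validated, , drop = FALSE] else ev
        m <- matchEvents(evScreen$time_s, truth, config$tolerance_ms)
        tn <- countTrueNegatives(filtered, truth, evScreen$time_s,
            config$tolerance_ms)
        screening <- screeningStats(m$TP, m$FP, tn, m$FN)
    }

    report <- list(
        config = config[setdiff(names(config), "simulation")],
        simulation = if (is.null(truth)) NULL else list(
            n_truth_events = nrow(truth),
            duration_s = duration(recording),
            fs_hz = samplingRate(recording)),
        detection = list(
            n_candidates = nrow(ev),
            n_validated = sum(ev$validated),
            n_dropped_boundary = spikes@nDroppedBoundary),
        waveforms = list(
            n = nrow(waveforms(wfs)),
            n_samples = ncol(waveforms(wfs)),
            alignment_offset = wfs@alignmentOffset,
            n_dropped = wfs@nDropped),
        sorting = if (is.null(sorting)) NULL else list(
            n_clusters = sorting@k,
            sizes = as.integer(sorting@sizes),
            n_singletons = sum(sorting@sizes == 1L),
            n_accepted = sum(sorting@accepted),
            n_noise_flagged = sum(sorting@isNoise),
            dispersions = sorting@dispersions),
        screening = if (is.null(screening)) NULL else list(
            TP = screening@TP, FP = screening@FP,
            TN = screening@TN, FN = screening@FN,
            Se = screening@Se, Sp = screening@Sp,
            PPV = screening@PPV, NPV = screening@NPV)
    )
    list(recording = recording, filtered = filtered,
        thresholds = thresholds, spikes = spikes, waveforms = wfs,
        sorting = sorting, screening = screening,
        reconstruction = reconstruction, report = report)
}

#' Write a run report (and resolved configuration) as JSON
#'
#' @param run the list returned by [runPipeline()].
#' @param path output JSON path.
#' @export
writeRunReport <- function(run, path) {
    rep <- run$report
    rep$config$sorting <- rep$config$sorting
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
        null = "null")
    invisible(path)
}
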