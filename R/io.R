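## Plain-format readers and writers: raw int16 traces with a JSON
## sidecar, and CSV tables for ground truth, events and thresholds.

#' Write a recording as raw int16 with a JSON sidecar
#'
#' The trace is quantized to signed 16-bit counts with the given gain
#' (microvolts per count); the sidecar records \code{fs_hz},
#' \code{gain_uv_per_count} and \code{n_channels}.
#'
#' @param rec a [Recording-class].
#' @param prefix output path prefix; writes \code{<prefix>.bin} and
#'   \code{<prefix>.json}.
#' @param gainUvPerCount quantization gain (default 0.1 uV/count).
#' @return the two file paths, invisibly.
#' @export
writeRawRecording <- function(rec, prefix, gainUvPerCount = 0.1) {
    counts <- as.integer(round(samples(rec) / gainUvPerCount))
    if (any(abs(counts) > .Machine$integer.max) ||
        any(abs(counts) > 32767L)) {
        stop("writeRawRecording: trace exceeds int16 range at this gain")
    }
    bin <- paste0(prefix, ".bin")
    js <- paste0(prefix, ".json")
    con <- file(bin, "wb")
    on.exit(close(con))
    writeBin(counts, con, size = 2L, endian = "little")
    jsonlite::write_json(list(fs_hz = samplingRate(rec),
        gain_uv_per_count = gainUvPerCount, n_channels = 1L,
        channel_id = rec@channelId, n_samples = nSamples(rec)),
        js, auto_unbox = TRUE, digits = NA)
    invisible(c(bin = bin, json = js))
}

#' Read a raw int16 recording with its JSON sidecar
#'
#' @param prefix path prefix used by [writeRawRecording()], or the
#'   \code{.bin} path itself (the sidecar is found by swapping the
#'   extension).
#' @return a [Recording-class] in microvolts.
#' @export
readRawRecording <- function(prefix) {
    bin <- if (grepl("\\.bin$", prefix)) prefix else paste0(prefix, ".bin")
    js <- sub("\\.bin$", ".json", bin)
    meta <- jsonlite::read_json(js, simplifyVector = TRUE)
    n <- file.size(bin) / 2L
    con <- file(bin, "rb")
    on.exit(close(con))
    counts <- readBin(con, "integer", n = n, size = 2L, signed = TRUE,
        endian = "little")
    Recording(counts * meta$gain_uv_per_count, meta$fs_hz,
        channelId = if (!is.null(meta$channel_id)) meta$channel_id else "ch1")
}

#' Read and write ground-truth event tables
#'
#' CSV with header \code{event_index,time_s,class_id,peak_amplitude_uv}.
#'
#' @param gt ground-truth data.frame (see [groundTruth()]).
#' @param path CSV path.
#' @return \code{readGroundTruth()} returns the data.frame.
#' @export
writeGroundTruth <- function(gt, path) {
    utils::write.csv(gt, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
    gt <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("event_index", "time_s", "class_id", "peak_amplitude_uv")
    if (!all(need %in% names(gt))) {
        stop("readGroundTruth: missing columns: ",
            paste(setdiff(need, names(gt)), collapse = ", "))
    }
    gt
}

#' Write detected events as CSV
#'
#' Columns \code{peak_index,time_s,polarity,peak_amplitude_uv,validated}.
#'
#' @param spikes a [SpikeEvents-class].
#' @param path CSV path.
#' @export
writeEvents <- function(spikes, path) {
    utils::write.csv(events(spikes), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write a threshold trace as CSV
#'
#' Columns \code{window_index,t_s,pos_uv,neg_uv,valid}.
#'
#' @param thresholds a [ThresholdTrace-class].
#' @param path CSV path.
#' @export
writeThresholds <- function(thresholds, path) {
    utils::write.csv(as.data.frame(thresholds), path, row.names = FALSE,
        quote = FALSE)
    invisible(path)
}

#' Write sorting labels as CSV
#'
#' Columns \code{event_index,cluster_id,accepted,is_noise}.
#'
#' @param sorting a [SpikeSorting-class].
#' @param wfs the sorted [WaveformSet-class].
#' @param path CSV path.
#' @export
writeClusterLabels <- function(sorting, wfs, path) {
    lab <- sorting@labels
    utils::write.csv(data.frame(
        event_index = wfs@events$peak_index,
        cluster_id = lab,
        accepted = sorting@accepted[lab],
        is_noise = sorting@isNoise[lab]), path,
        row.names = FALSE, quote = FALSE)
    invisible(path)
}
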