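## Bipolar threshold crossing, the +/-1 ms peak-validation rule and
## 2 ms peak-aligned waveform extraction.

## Per-sample threshold vectors from a per-window ThresholdTrace:
## zero-order hold of the most recent valid pair. By default the first
## valid pair is also held backward over the initialization span (the
## offline convention); skipInitial = TRUE instead leaves the
## pre-initialization samples undetectable (streaming behaviour).
sampleThresholds <- function(thresholds, nSamples, skipInitial = FALSE) {
    wl <- thresholds@windowLen
    nw <- length(thresholds@pos)
    pos <- thresholds@pos
    neg <- thresholds@neg
    valid <- thresholds@valid
    if (!any(valid)) {
        return(list(pos = rep(NA_real_, nSamples),
            neg = rep(NA_real_, nSamples)))
    }
    first <- which(valid)[1L]
    # carry the last valid value forward
    idx <- cummax(ifelse(valid, seq_len(nw), 0L))
    p <- n <- rep(NA_real_, nw)
    held <- idx > 0L
    p[held] <- pos[idx[held]]
    n[held] <- neg[idx[held]]
    if (!skipInitial && first > 1L) {
        p[seq_len(first - 1L)] <- pos[first]
        n[seq_len(first - 1L)] <- neg[first]
    }
    # expand to samples; the tail beyond the last full window keeps the
    # final threshold
    posS <- rep(p, each = wl)
    negS <- rep(n, each = wl)
    if (length(posS) < nSamples) {
        posS <- c(posS, rep(p[nw], nSamples - length(posS)))
        negS <- c(negS, rep(n[nw], nSamples - length(negS)))
    }
    list(pos = posS[seq_len(nSamples)], neg = negS[seq_len(nSamples)])
}

#' Detect threshold crossings
#'
#' Scans a filtered trace against per-window bipolar thresholds and
#' emits one candidate per contiguous supra-threshold excursion, located
#' at the extremum of the excursion (earliest sample on ties), with the
#' extremum's polarity.
#'
#' @param filtered a band-pass filtered [Recording-class].
#' @param thresholds a [ThresholdTrace-class] for the same trace.
#' @param skipInitial if TRUE, samples before the estimator initialized
#'   are not scanned; by default the first valid threshold is applied
#'   retroactively over the initialization span.
#' @return a [SpikeEvents-class] with \code{validated = FALSE} for all
#'   events (see [validateSpikes()]).
#' @export
detectCrossings <- function(filtered, thresholds, skipInitial = FALSE) {
    x <- samples(filtered)
    th <- sampleThresholds(thresholds, length(x), skipInitial)
    above <- !is.na(th$pos) & (x > th$pos | x < th$neg)
    events <- emptyEvents()
    if (any(above)) {
        r <- rle(above)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        runs <- which(r$values)
        peakIdx <- integer(length(runs))
        for (j in seq_along(runs)) {
            s <- starts[runs[j]]
            e <- ends[runs[j]]
            seg <- abs(x[s:e])
            peakIdx[j] <- s + which.max(seg) - 1L  # earliest tie wins
        }
        events <- data.frame(
            peak_index = peakIdx,
            time_s = (peakIdx - 1L) / samplingRate(filtered),
            polarity = ifelse(x[peakIdx] >= 0, "+", "-"),
            peak_amplitude_uv = x[peakIdx],
            validated = FALSE)
    }
    new("SpikeEvents", events = events, fsHz = samplingRate(filtered))
}

emptyEvents <- function() {
    data.frame(peak_index = integer(), time_s = numeric(),
        polarity = character(), peak_amplitude_uv = numeric(),
        validated = logical())
}

#' Validate a single candidate peak
#'
#' The two-part rule applied in a +/-\code{windowMs} window around the
#' candidate: (a) the candidate must be the highest peak of either
#' polarity (largest absolute value in the window; an equal-amplitude
#' sample at an earlier index defeats it), and (b) 50% of its amplitude
#' must exceed the amplitude of every other same-polarity local peak in
#' the window. Same-polarity competitors are plateau-aware strict local
#' extrema, not raw samples. Candidates whose window extends past the
#' trace boundary are discarded (return NA).
#'
#' @param peakIndex 1-based sample index of the candidate.
#' @param filtered a filtered [Recording-class] or numeric vector.
#' @param windowMs half-width of the test window in milliseconds.
#' @param fsHz sampling rate (needed for plain vectors).
#' @return TRUE/FALSE, or NA if the window leaves the trace.
#' @export
validatePeak <- function(peakIndex, filtered, windowMs = 1, fsHz = NULL) {
    if (is(filtered, "Recording")) {
        fsHz <- samplingRate(filtered)
        x <- samples(filtered)
    } else x <- filtered
    half <- as.integer(round(windowMs / 1000 * fsHz))
    lo <- peakIndex - half
    hi <- peakIndex + half
    if (lo < 1L || hi > length(x)) return(NA)  # boundary: discard
    w <- x[lo:hi]
    a <- abs(x[peakIndex])
    absw <- abs(w)
    # (a) highest peak of either polarity; ties resolved to the
    # earliest sample
    if (any(absw > a)) return(FALSE)
    ties <- which(absw == a)
    if (ties[1L] + lo - 1L < peakIndex) return(FALSE)
    # (b) half the amplitude must beat every other same-polarity local
    # peak in the window
    pk <- if (x[peakIndex] >= 0) localMaxima(w) else localMaxima(-w)
    pk <- pk[pk + lo - 1L != peakIndex]
    if (length(pk)) {
        other <- abs(w[pk])
        other <- other[if (x[peakIndex] >= 0) w[pk] > 0 else w[pk] < 0]
        if (length(other) && any(0.5 * a <= other)) return(FALSE)
    }
    TRUE
}

#' Validate detected candidates
#'
#' Applies [validatePeak()] to every candidate; validation of each
#' candidate depends only on the trace, so the result is independent of
#' processing order. Boundary candidates are dropped and counted.
#'
#' @param spikes a [SpikeEvents-class] from [detectCrossings()].
#' @param filtered the filtered [Recording-class] the candidates came
#'   from.
#' @param windowMs validation half-window in milliseconds.
#' @param keepLarger if TRUE, when the literal 50% rule rejects both of
#'   two comparable same-polarity peaks, the larger one is retained
#'   (off by default; the literal rule rejects both).
#' @return a [SpikeEvents-class] with updated \code{validated} flags and
#'   \code{nDroppedBoundary}.
#' @export
validateSpikes <- function(spikes, filtered, windowMs = 1,
        keepLarger = FALSE) {
    ev <- events(spikes)
    if (nrow(ev) == 0L) return(spikes)
    flags <- vapply(ev$peak_index, validatePeak, logical(1),
        filtered = filtered, windowMs = windowMs)
    dropped <- sum(is.na(flags))
    if (keepLarger && any(!is.na(flags) & !flags)) {
        x <- samples(filtered)
        half <- as.integer(round(windowMs / 1000 * samplingRate(filtered)))
        rej <- which(!is.na(flags) & !flags)
        for (i in rej) {
            p <- ev$peak_index[i]
            same <- which(ev$polarity == ev$polarity[i] &
                abs(ev$peak_index - p) <= half)
            # keep the candidate if it is the largest same-polarity
            # candidate in its own window and passed the either-polarity
            # test
            if (all(abs(ev$peak_amplitude_uv[same]) <=
                    abs(ev$peak_amplitude_uv[i]))) {
                w <- x[max(1L, p - half):min(length(x), p + half)]
                if (max(abs(w)) <= abs(x[p])) flags[i] <- TRUE
            }
        }
    }
    keep <- !is.na(flags)
    ev <- ev[keep, , drop = FALSE]
    ev$validated <- flags[keep]
    rownames(ev) <- NULL
    new("SpikeEvents", events = ev, fsHz = spikes@fsHz,
        nDroppedBoundary = as.integer(dropped))
}

#' Detect spikes: threshold crossing plus optional validation
#'
#' Convenience wrapper running [detectCrossings()] and, when
#' \code{validate = TRUE}, [validateSpikes()].
#'
#' @param x a filtered [Recording-class].
#' @param thresholds a [ThresholdTrace-class].
#' @param validate apply the +/-1 ms peak-validation rule.
#' @param ... passed to [detectCrossings()] and [validateSpikes()]
#'   (\code{skipInitial}, \code{windowMs}, \code{keepLarger}).
#' @return a [SpikeEvents-class].
#' @rdname detectSpikes
#' @export
setMethod("detectSpikes", "Recording",
    function(x, thresholds, validate = TRUE, skipInitial = FALSE,
            windowMs = 1, keepLarger = FALSE) {
        sp <- detectCrossings(x, thresholds, skipInitial = skipInitial)
        if (validate) {
            sp <- validateSpikes(sp, x, windowMs = windowMs,
                keepLarger = keepLarger)
        }
        sp
    })

#' Extract peak-aligned waveforms
#'
#' Cuts a symmetric \code{windowMs} (default 2 ms) snippet around each
#' event and aligns rows on the tallest peak: the largest-absolute
#' sample of each snippet sits at column \code{floor(c/2) + 1} (column
#' 26 of 50 at 25 kHz). Events whose window would leave the trace are
#' dropped and counted.
#'
#' @param x the filtered [Recording-class].
#' @param events a [SpikeEvents-class]; only validated events are used
#'   unless \code{validatedOnly = FALSE}.
#' @param windowMs full window length in milliseconds.
#' @param validatedOnly restrict to validated events.
#' @return a [WaveformSet-class].
#' @rdname extractWaveforms
#' @export
setMethod("extractWaveforms", "Recording",
    function(x, events, windowMs = 2, validatedOnly = TRUE) {
        fs <- samplingRate(x)
        sig <- samples(x)
        cLen <- as.integer(round(windowMs / 1000 * fs))
        pre <- cLen %/% 2L
        offset <- pre + 1L
        ev <- slot(events, "events")
        if (validatedOnly) ev <- ev[ev$validated, , drop = FALSE]
        keep <- logical(nrow(ev))
        peaks <- ev$peak_index
        # re-center on the tallest |peak| within the window until stable
        # (for validated events the event peak already is the tallest)
        for (i in seq_len(nrow(ev))) {
            p <- peaks[i]
            ok <- TRUE
            repeat {  # each re-center strictly raises max|seg|: terminates
                if (p - pre < 1L || p + (cLen - pre - 1L) > length(sig)) {
                    ok <- FALSE
                    break
                }
                seg <- sig[(p - pre):(p + cLen - pre - 1L)]
                m <- which.max(abs(seg))
                p2 <- p - pre + m - 1L
                if (p2 == p) break
                p <- p2
            }
            if (ok) {
                peaks[i] <- p
                keep[i] <- TRUE
            }
        }
        ev <- ev[keep, , drop = FALSE]
        peaks <- peaks[keep]
        ev$peak_index <- peaks  # aligned (possibly re-centred) peaks
        ev$time_s <- (peaks - 1L) / fs
        wf <- matrix(0, nrow = nrow(ev), ncol = cLen)
        for (i in seq_len(nrow(ev))) {
            wf[i, ] <- sig[(peaks[i] - pre):(peaks[i] + cLen - pre - 1L)]
        }
        rownames(ev) <- NULL
        new("WaveformSet", waveforms = wf, alignmentOffset = offset,
            fsHz = fs, events = ev, nDropped = as.integer(sum(!keep)))
    })
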