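## Synthetic MEA recording generator: triangular action potentials and
## overlapped complexes in band-limited Gaussian noise at a target SNR,
## with a ground-truth event table.

#' Triangular action-potential template
#'
#' A symmetric triangular ramp of \code{nSamples} samples with its apex
#' (signed \code{peakAmplitudeUv}) at the centre sample, i.e. 1-based
#' position \code{floor(nSamples / 2) + 1}; the off-template baseline
#' is zero.
#'
#' @param peakAmplitudeUv positive peak amplitude in microvolts.
#' @param polarity "+" or "-".
#' @param nSamples template length in samples (default 20, i.e. 0.8 ms
#'   at 25 kHz).
#' @return a list with \code{samples}, \code{peak_offset} (1-based index
#'   of the apex), \code{polarity} and \code{peak_amplitude_uv}.
#' @examples
#' tpl <- makeTriangleTemplate(100, "+")
#' which.max(tpl$samples) # 11
#' @export
makeTriangleTemplate <- function(peakAmplitudeUv, polarity = c("+", "-"),
        nSamples = 20L) {
    polarity <- match.arg(polarity)
    if (!is.finite(peakAmplitudeUv) || peakAmplitudeUv <= 0) {
        stop("makeTriangleTemplate: peak amplitude must be positive")
    }
    if (nSamples < 3L) stop("makeTriangleTemplate: need at least 3 samples")
    apex <- floor(nSamples / 2) + 1L
    half <- ceiling(nSamples / 2)
    i <- seq_len(nSamples)
    v <- peakAmplitudeUv * pmax(0, 1 - abs(i - apex) / half)
    if (polarity == "-") v <- -v
    list(samples = v, peak_offset = apex, polarity = polarity,
        peak_amplitude_uv = peakAmplitudeUv)
}

#' Overlapped-complex template
#'
#' Sums a base triangular template with a temporally shifted copy
#' (optionally of opposite polarity), emulating the multi-shaped action
#' potentials produced by overlapping units. The result has length
#' \code{length(base) + shiftSamples}.
#'
#' @param base a template from [makeTriangleTemplate()].
#' @param shiftSamples shift of the second component, in samples;
#'   must satisfy \code{0 < shiftSamples < length(base$samples)} so the
#'   two components overlap.
#' @param secondPolarity polarity of the shifted copy relative to
#'   microvolt zero: "+" keeps the base's sign, "-" flips it.
#' @param secondScale amplitude scale of the shifted copy (default 1).
#'   A same-polarity complex with equal amplitudes and a shift equal to
#'   the apex half-width degenerates to a flat top whose tallest-peak
#'   time stamp is undefined; a scale below 1 keeps the tallest peak
#'   unique.
#' @return a template list as in [makeTriangleTemplate()];
#'   \code{peak_offset} points at the earliest tallest |peak|.
#' @examples
#' base <- makeTriangleTemplate(70, "+")
#' cx <- makeComplexTemplate(base, 10, "-") # biphasic: +70 then -70
#' range(cx$samples)
#' @export
makeComplexTemplate <- function(base, shiftSamples,
        secondPolarity = c("+", "-"), secondScale = 1) {
    secondPolarity <- match.arg(secondPolarity)
    nb <- length(base$samples)
    if (shiftSamples <= 0 || shiftSamples >= nb) {
        stop("makeComplexTemplate: shift must be in (0, template length) ",
            "so the components overlap")
    }
    if (!is.finite(secondScale) || secondScale <= 0) {
        stop("makeComplexTemplate: secondScale must be positive")
    }
    n <- nb + shiftSamples
    v <- numeric(n)
    v[seq_len(nb)] <- base$samples
    second <- secondScale *
        (if (secondPolarity == "-") -base$samples else base$samples)
    v[shiftSamples + seq_len(nb)] <- v[shiftSamples + seq_len(nb)] + second
    peak <- which.max(abs(v))  # earliest tie wins
    list(samples = v, peak_offset = peak,
        polarity = if (v[peak] >= 0) "+" else "-",
        peak_amplitude_uv = abs(v[peak]))
}

#' Default simulated waveform classes
#'
#' Five waveform classes spanning the 40-100 microvolt peak range:
#' simple positive and negative triangles (A, B), a low-amplitude
#' positive triangle (C), an overlapped same-polarity complex (D) and a
#' biphasic complex (E). D uses a 0.5 ms shift and a 0.8 amplitude
#' scale on its second component so the complex shows two distinct
#' peaks with a unique tallest one (equal amplitudes at a shift equal
#' to the apex half-width collapse to a flat top, leaving the tallest
#' peak -- the alignment time stamp -- undefined); the biphasic E uses
#' a 0.4 ms shift.
#'
#' @param fsHz sampling rate in Hz (sets the complex shifts in samples).
#' @return named list of templates.
#' @export
defaultTemplates <- function(fsHz = 25000) {
    list(
        A = makeTriangleTemplate(80, "+"),
        B = makeTriangleTemplate(80, "-"),
        C = makeTriangleTemplate(45, "+"),
        D = makeComplexTemplate(makeTriangleTemplate(70, "+"),
            round(0.0005 * fsHz), "+", secondScale = 0.8),
        E = makeComplexTemplate(makeTriangleTemplate(70, "+"),
            round(0.0004 * fsHz), "-")
    )
}

#' Simulation configuration
#'
#' @param durationSec record length in seconds.
#' @param fsHz sampling rate in Hz.
#' @param nEvents total number of spike events (simple and complex; an
#'   overlapped complex counts as one event).
#' @param classMix named proportions over the waveform classes.
#' @param snrDb target signal-to-noise ratio in dB.
#' @param noiseBandHz band of the noise (low, high) in Hz.
#' @param minSeparationMs minimum separation between event onsets, ms.
#' @param templates waveform class templates (see [defaultTemplates()]).
#' @param seed integer seed, or NULL to use the session RNG.
#' @return a validated configuration list.
#' @export
simulationConfig <- function(durationSec = 60, fsHz = 25000,
        nEvents = 600L, classMix = NULL, snrDb = 5,
        noiseBandHz = c(150, 2500), minSeparationMs = 5,
        templates = defaultTemplates(fsHz), seed = NULL) {
    if (is.null(classMix)) {
        classMix <- rep(1 / length(templates), length(templates))
        names(classMix) <- names(templates)
    }
    if (is.null(names(classMix)) ||
        !setequal(names(classMix), names(templates))) {
        stop("classMix must be named after the templates")
    }
    classMix <- classMix[names(templates)] / sum(classMix)
    if (!is.finite(snrDb)) stop("snrDb must be finite")
    if (noiseBandHz[2] >= fsHz / 2) {
        stop("noise band must lie below the Nyquist frequency")
    }
    minSep <- round(minSeparationMs / 1000 * fsHz)
    if (nEvents * minSep > durationSec * fsHz) {
        stop("infeasible configuration: nEvents x minSeparation exceeds ",
            "the record duration")
    }
    list(duration_s = durationSec, fs_hz = fsHz, n_events = as.integer(nEvents),
        class_mix = classMix, snr_db = snrDb, noise_band_hz = noiseBandHz,
        min_separation_ms = minSeparationMs, templates = templates,
        seed = seed)
}

#' Generate the clean (noise-free) spike train
#'
#' Inserts \code{n_events} templates at uniformly drawn positions with a
#' rejection rule enforcing the minimum separation; class labels are
#' multinomial draws from \code{class_mix}. Reproducible from the seed.
#'
#' @param config a list from [simulationConfig()].
#' @return list with \code{recording} (a [Recording-class] of the clean
#'   trace) and \code{groundTruth} (data.frame
#'   \code{event_index,time_s,class_id,peak_amplitude_uv}, sorted by
#'   \code{event_index}, which is the 1-based sample of the event's
#'   tallest peak).
#' @export
generateCleanSignal <- function(config) {
    withSeed(config$seed, {
        n <- round(config$duration_s * config$fs_hz)
        trace <- numeric(n)
        minSep <- round(config$min_separation_ms / 1000 * config$fs_hz)
        maxLen <- max(vapply(config$templates,
            function(t) length(t$samples), integer(1)))
        nEv <- config$n_events
        if (nEv == 0L) {
            return(list(
                recording = Recording(trace, config$fs_hz, "sim"),
                groundTruth = data.frame(event_index = integer(),
                    time_s = numeric(), class_id = character(),
                    peak_amplitude_uv = numeric())))
        }
        # uniform onset positions with rejection to enforce separation
        starts <- integer(0)
        tries <- 0L
        lim <- n - maxLen
        while (length(starts) < nEv) {
            cand <- sample.int(lim, 1L)
            if (!length(starts) || all(abs(starts - cand) >= minSep)) {
                starts <- c(starts, cand)
            }
            tries <- tries + 1L
            if (tries > 1000L * nEv) {
                stop("could not place events at the requested separation")
            }
        }
        starts <- sort(starts)
        cls <- sample(names(config$class_mix), nEv, replace = TRUE,
            prob = config$class_mix)
        peakIdx <- integer(nEv)
        peakAmp <- numeric(nEv)
        for (i in seq_len(nEv)) {
            tpl <- config$templates[[cls[i]]]
            span <- starts[i] + seq_along(tpl$samples) - 1L
            trace[span] <- trace[span] + tpl$samples
            peakIdx[i] <- starts[i] + tpl$peak_offset - 1L
            peakAmp[i] <- tpl$peak_amplitude_uv
        }
        gt <- data.frame(event_index = peakIdx,
            time_s = (peakIdx - 1L) / config$fs_hz,
            class_id = cls, peak_amplitude_uv = peakAmp)
        gt <- gt[order(gt$event_index), , drop = FALSE]
        rownames(gt) <- NULL
        list(recording = Recording(trace, config$fs_hz, "sim"),
            groundTruth = gt)
    })
}

#' Band-limited unit-RMS Gaussian noise
#'
#' White Gaussian noise, band-pass filtered with a 2nd-order Butterworth
#' filter and normalized to unit RMS.
#'
#' @param nSamples length of the noise vector.
#' @param fsHz sampling rate in Hz.
#' @param bandHz (low, high) passband edges in Hz.
#' @param seed integer seed, or NULL.
#' @return numeric vector with RMS exactly 1.
#' @export
generateBandlimitedNoise <- function(nSamples, fsHz,
        bandHz = c(150, 2500), seed = NULL) {
    if (bandHz[1] <= 0 || bandHz[2] >= fsHz / 2 || bandHz[1] >= bandHz[2]) {
        stop("noise band must satisfy 0 < low < high < fs/2")
    }
    withSeed(seed, {
        w <- stats::rnorm(nSamples)
        b <- signal::butter(2, bandHz / (fsHz / 2), type = "pass")
        x <- as.numeric(signal::filter(b, w))
        x <- x - mean(x)
        x / windowRMS(x)
    })
}

#' Mix a clean signal with noise at an exact SNR
#'
#' Scales the noise so that \code{20 * log10(RMS(clean) / RMS(noise))}
#' equals \code{snrDb} exactly, and returns the sum.
#'
#' @param clean a [Recording-class] (must not be identically zero).
#' @param noise numeric vector, same length as the clean trace.
#' @param snrDb target SNR in dB.
#' @return list with \code{recording} (clean + scaled noise) and
#'   \code{scaledNoise}.
#' @export
mixAtSNR <- function(clean, noise, snrDb) {
    x <- samples(clean)
    if (length(noise) != length(x)) stop("mixAtSNR: length mismatch")
    rc <- windowRMS(x)
    if (rc == 0) stop("mixAtSNR: clean signal has zero power; SNR undefined")
    rn <- windowRMS(noise)
    if (rn == 0) stop("mixAtSNR: noise has zero power")
    alpha <- rc / (rn * 10^(snrDb / 20))
    scaled <- alpha * noise
    list(recording = Recording(x + scaled, samplingRate(clean),
        clean@channelId), scaledNoise = scaled)
}

#' Measure the SNR of a clean/noise decomposition
#'
#' @param clean a [Recording-class] or numeric vector.
#' @param noiseComponent numeric vector of equal length.
#' @return SNR in dB: \code{20 * log10(RMS(clean) / RMS(noise))}.
#' @export
measureSNR <- function(clean, noiseComponent) {
    x <- if (is(clean, "Recording")) samples(clean) else as.numeric(clean)
    if (length(noiseComponent) != length(x)) stop("measureSNR: length mismatch")
    rn <- windowRMS(noiseComponent)
    if (rn == 0) stop("measureSNR: noise component has zero power")
    20 * log10(windowRMS(x) / rn)
}

#' Filtered reference waveforms of the template classes
#'
#' What each waveform class looks like at the point waveforms are
#' extracted: the template inserted in a zero trace, passed through the
#' causal band-pass filter, and cut out peak-aligned. Useful for
#' matching sorted cluster means back to their generating classes.
#'
#' @param templates named template list (see [defaultTemplates()]).
#' @param fsHz sampling rate in Hz.
#' @param windowMs extraction window in milliseconds.
#' @param lowHz,highHz,order filter settings (must match the pipeline's).
#' @return matrix with one column per class, \code{round(windowMs/1000 *
#'   fsHz)} rows, peak aligned as in [extractWaveforms()].
#' @export
referenceWaveforms <- function(templates = defaultTemplates(fsHz),
        fsHz = 25000, windowMs = 2, lowHz = 150, highHz = 2500,
        order = 2) {
    cLen <- as.integer(round(windowMs / 1000 * fsHz))
    pre <- cLen %/% 2L
    pad <- as.integer(round(0.2 * fsHz))  # let the filter settle
    out <- vapply(templates, function(t) {
        tr <- numeric(2L * pad)
        tr[pad + seq_along(t$samples)] <- t$samples
        f <- samples(bandpassFilter(Recording(tr, fsHz), lowHz, highHz,
            order))
        p <- which.max(abs(f))
        f[(p - pre):(p + cLen - pre - 1L)]
    }, numeric(cLen))
    out
}

#' Simulate a ground-truthed MEA recording
#'
#' End-to-end simulation: clean spike train (see
#' [generateCleanSignal()]), band-limited Gaussian noise, exact-SNR mix.
#' Defaults reproduce the benchmark conditions: 60 s at 25 kHz, 600
#' events over five waveform classes, noise band 150-2500 Hz, 5 dB SNR.
#'
#' @param config a list from [simulationConfig()]; or pass the
#'   individual arguments of [simulationConfig()] through \code{...}.
#' @param seed integer seed (overrides \code{config$seed} if given).
#' @param ... arguments forwarded to [simulationConfig()] when
#'   \code{config} is NULL.
#' @return a [SimulatedRecording-class].
#' @examples
#' sim <- simulateRecording(seed = 1, durationSec = 2, nEvents = 20L)
#' nrow(groundTruth(sim))
#' @export
simulateRecording <- function(config = NULL, seed = NULL, ...) {
    if (is.null(config)) config <- simulationConfig(...)
    if (!is.null(seed)) config$seed <- seed
    clean <- generateCleanSignal(config)
    noiseSeed <- if (is.null(config$seed)) NULL else config$seed + 1L
    noise <- generateBandlimitedNoise(nSamples(clean$recording),
        config$fs_hz, config$noise_band_hz, seed = noiseSeed)
    mixed <- mixAtSNR(clean$recording, noise, config$snr_db)
    new("SimulatedRecording",
        samples = samples(mixed$recording), fsHz = config$fs_hz,
        channelId = "sim", t0Sec = 0,
        clean = samples(clean$recording),
        noiseComponent = mixed$scaledNoise,
        groundTruth = clean$groundTruth,
        config = config)
}
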