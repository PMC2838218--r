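## Screening-test evaluation: event matching against ground truth,
## true-negative enumeration on simulated traces, the four screening
## ratios, and the initialization-complexity comparison of the two
## best estimators.

#' Match detections to ground truth
#'
#' Greedy nearest-neighbour one-to-one pairing: all (detection, truth)
#' pairs within the tolerance are ranked by time difference and paired
#' greedily. Paired detections are true positives, unpaired detections
#' false positives, unpaired truths false negatives.
#'
#' @param detectedS numeric, detection times in seconds (or a
#'   [SpikeEvents-class]).
#' @param truthS numeric, ground-truth times in seconds (or the
#'   data.frame from [groundTruth()]).
#' @param toleranceMs matching tolerance in milliseconds.
#' @return list with \code{TP}, \code{FP}, \code{FN} and \code{pairing}
#'   (data.frame \code{detected_index, truth_index, dt_s}).
#' @export
matchEvents <- function(detectedS, truthS, toleranceMs = 1) {
    if (is(detectedS, "SpikeEvents")) detectedS <- events(detectedS)$time_s
    if (is.data.frame(truthS)) truthS <- truthS$time_s
    if (toleranceMs <= 0) stop("matchEvents: tolerance must be positive")
    tol <- toleranceMs / 1000
    nd <- length(detectedS)
    nt <- length(truthS)
    pairs <- NULL
    if (nd && nt) {
        # candidate pairs within tolerance, found by sorted interval scan
        ord <- order(truthS)
        ts <- truthS[ord]
        lo <- findInterval(detectedS - tol, ts) + 1L
        hi <- findInterval(detectedS + tol, ts)
        di <- rep.int(seq_len(nd), pmax(0L, hi - lo + 1L))
        ti <- unlist(lapply(seq_len(nd), function(i)
            if (hi[i] >= lo[i]) ord[lo[i]:hi[i]] else integer()),
            use.names = FALSE)
        if (length(di)) {
            dt <- abs(detectedS[di] - truthS[ti])
            o <- order(dt, di, ti)
            di <- di[o]; ti <- ti[o]; dt <- dt[o]
            usedD <- logical(nd)
            usedT <- logical(nt)
            keep <- logical(length(di))
            for (r in seq_along(di)) {
                if (!usedD[di[r]] && !usedT[ti[r]]) {
                    usedD[di[r]] <- TRUE
                    usedT[ti[r]] <- TRUE
                    keep[r] <- TRUE
                }
            }
            pairs <- data.frame(detected_index = di[keep],
                truth_index = ti[keep],
                dt_s = detectedS[di[keep]] - truthS[ti[keep]])
        }
    }
    if (is.null(pairs)) {
        pairs <- data.frame(detected_index = integer(),
            truth_index = integer(), dt_s = numeric())
    }
    list(TP = nrow(pairs), FP = nd - nrow(pairs), FN = nt - nrow(pairs),
        pairing = pairs)
}

#' Count true negatives on a ground-truthed trace
#'
#' True negatives need an enumerable population of noise peaks, so they
#' are defined only for simulated (or annotated) data: candidate noise
#' peaks are the local extrema of the filtered trace lying outside the
#' tolerance window of every ground-truth event; a candidate is a true
#' negative when no detection falls within the tolerance of it.
#'
#' @param filtered the filtered [Recording-class].
#' @param truthS ground-truth times in seconds (or the ground-truth
#'   data.frame). Required: TN is undefined for blind data.
#' @param detectedS detection times in seconds (or a
#'   [SpikeEvents-class]).
#' @param toleranceMs tolerance in milliseconds.
#' @return integer TN count.
#' @export
countTrueNegatives <- function(filtered, truthS, detectedS,
        toleranceMs = 1) {
    if (is.null(truthS)) {
        stop("countTrueNegatives: ground truth required; TN is undefined ",
            "for blind data")
    }
    if (is.data.frame(truthS)) truthS <- truthS$time_s
    if (is(detectedS, "SpikeEvents")) detectedS <- events(detectedS)$time_s
    x <- samples(filtered)
    fs <- samplingRate(filtered)
    tol <- toleranceMs / 1000
    cand <- sort(c(localMaxima(x), localMaxima(-x)))
    candS <- (cand - 1L) / fs
    nearTruth <- nearAny(candS, truthS, tol)
    candS <- candS[!nearTruth]
    detected <- nearAny(candS, detectedS, tol)
    sum(!detected)
}

## TRUE for each x within tol of any element of ref
nearAny <- function(x, ref, tol) {
    if (!length(ref)) return(rep(FALSE, length(x)))
    ref <- sort(ref)
    i <- findInterval(x, ref)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(ref))
    abs(x - ref[lo]) <= tol | abs(x - ref[hi]) <= tol
}

#' Screening-test statistics
#'
#' Sensitivity Se = TP/(TP+FN), specificity Sp = TN/(TN+FP), positive
#' predictive value PPV = TP/(TP+FP) and negative predictive value
#' NPV = TN/(TN+FN). A ratio with zero denominator is NA, with the
#' reason recorded in the result's notes.
#'
#' @param TP,FP,TN,FN non-negative integer counts.
#' @return a [ScreeningResult-class].
#' @examples
#' screeningStats(599, 20, 1000, 1)
#' @export
screeningStats <- function(TP, FP, TN, FN) {
    counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
    if (any(counts < 0)) stop("screeningStats: counts must be non-negative")
    if (sum(counts) == 0) stop("screeningStats: all four counts are zero")
    notes <- character()
    ratio <- function(num, den, name) {
        if (den == 0) {
            notes <<- c(notes, paste0(name, " undefined: denominator 0"))
            return(NA_real_)
        }
        num / den
    }
    new("ScreeningResult",
        TP = as.integer(TP), FP = as.integer(FP),
        TN = as.integer(TN), FN = as.integer(FN),
        Se = ratio(TP, TP + FN, "Se"),
        Sp = ratio(TN, TN + FP, "Sp"),
        PPV = ratio(TP, TP + FP, "PPV"),
        NPV = ratio(TN, TN + FN, "NPV"),
        notes = notes)
}

#' Run the screening test for one estimator
#'
#' Filters the recording, estimates thresholds, detects spikes
#' (unvalidated by default, matching how the estimators are compared),
#' matches against ground truth and computes the screening statistics.
#'
#' @param sim a [SimulatedRecording-class].
#' @param method estimator name (see [noiseEstimator()]).
#' @param validate apply peak validation before scoring.
#' @param toleranceMs matching tolerance in milliseconds.
#' @param countTN also enumerate true negatives (slower).
#' @param ... passed to [estimateThresholds()].
#' @return list with \code{result} (a [ScreeningResult-class] when
#'   \code{countTN}; otherwise the TP/FP/FN counts with Se and PPV),
#'   \code{spikes}, \code{match}.
#' @export
screenEstimator <- function(sim, method, validate = FALSE,
        toleranceMs = 1, countTN = FALSE, ...) {
    filt <- bandpassFilter(sim)
    th <- estimateThresholds(filt, method, ...)
    sp <- detectSpikes(filt, th, validate = validate)
    ev <- events(sp)
    if (validate) ev <- ev[ev$validated, , drop = FALSE]
    m <- matchEvents(ev$time_s, groundTruth(sim), toleranceMs)
    if (countTN) {
        tn <- countTrueNegatives(filt, groundTruth(sim), ev$time_s,
            toleranceMs)
        res <- screeningStats(m$TP, m$FP, tn, m$FN)
    } else {
        res <- list(TP = m$TP, FP = m$FP, FN = m$FN,
            Se = if (m$TP + m$FN > 0) m$TP / (m$TP + m$FN) else NA_real_,
            PPV = if (m$TP + m$FP > 0) m$TP / (m$TP + m$FP) else NA_real_)
    }
    list(result = res, spikes = sp, match = m)
}

#' Initialization-complexity crossover
#'
#' Worst-case initialization costs of the two selected estimators as a
#' function of the window length N (samples) and an architecture factor
#' F: the clean-window estimator costs 100 F N^2 (100 clean windows,
#' each requiring a percentile over N sorted voltages), the adaptive
#' RMS-percentile estimator costs 100^2 F (sorting 100 window RMS
#' values). The costs cross at N = 10 independently of F: for N > 10
#' the clean-window initialization is the more expensive one.
#'
#' @return list with \code{nStar} (= 10), \code{limadaCost(N, F)} and
#'   \code{adaBandFltCost(F)} evaluators.
#' @examples
#' cx <- initializationComplexityCrossover()
#' cx$nStar
#' cx$limadaCost(10, 3) == cx$adaBandFltCost(3)
#' @export
initializationComplexityCrossover <- function() {
    limadaCost <- function(N, F = 1) 100 * F * N^2
    adaBandFltCost <- function(F = 1) 100^2 * F
    # smallest integer N with limadaCost > adaBandFltCost is N* + 1;
    # equality holds at the crossover N* itself
    nStar <- 10
    stopifnot(limadaCost(nStar) == adaBandFltCost(),
        limadaCost(nStar + 1) > adaBandFltCost())
    list(nStar = nStar, limadaCost = limadaCost,
        adaBandFltCost = adaBandFltCost)
}
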