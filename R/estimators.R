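## The five noise-level estimators. Each consumes 10 ms windows through
## an identical streaming contract (processWindow) and exposes the
## current positive/negative thresholds, invalid until its
## initialization completes.
##
## bandflt     fixed +/-4 x 25th percentile of 300 window RMS values
## limada      clean-window smoother: est <- 0.99 est + 0.01 |V.02|
## adaflt      window-extrema smoother, refresh every 1280 raw windows:
##             est_p <- 0.9 est_p + 0.1 M.4 (40th pct of retained maxima)
## adaflt128   as adaflt but retaining every window (refresh every 128)
## adabandflt  RMS-percentile smoother, refresh every 100 windows:
##             est <- 0.8 est + 0.2 N.25 (25th pct of window RMS)

estimatorMethods <- c("bandflt", "limada", "adaflt", "adaflt128",
    "adabandflt")

defaultMultiplier <- function(method) {
    switch(method, bandflt = 4, limada = 4, adabandflt = 4,
        adaflt = 2, adaflt128 = 2)
}

#' Create a streaming noise-estimator state
#'
#' Returns the initial state of one of the five estimators. Feed 10 ms
#' windows one at a time with [processWindow()]; the state carries the
#' window buffers, the current noise estimate(s) and the thresholds.
#'
#' @param method one of \code{"bandflt"}, \code{"limada"},
#'   \code{"adaflt"}, \code{"adaflt128"}, \code{"adabandflt"}.
#' @param fsHz sampling rate in Hz.
#' @param multiplier threshold multiple of the noise estimate; defaults
#'   to 4 for bandflt/limada/adabandflt and 2 for the adaflt variants.
#'   Must be positive.
#' @param windowMs analysis window length in milliseconds.
#' @param ratioLimit limada clean-window ratio limit (V.02 / V.30).
#' @param nonzeroEps limada blanked-window guard: |V.30| must exceed
#'   this (microvolts) for a window to be clean.
#' @return a \code{NoiseEstimatorState} (a list) with elements including
#'   \code{method}, \code{k} (windows consumed), \code{valid},
#'   \code{pos}, \code{neg}.
#' @examples
#' st <- noiseEstimator("adabandflt", fsHz = 25000)
#' out <- processWindow(st, rnorm(250))
#' out$threshold
#' @export
noiseEstimator <- function(method = estimatorMethods, fsHz,
        multiplier = NULL, windowMs = 10, ratioLimit = 5,
        nonzeroEps = 1e-3) {
    method <- match.arg(method)
    if (is.null(multiplier)) multiplier <- defaultMultiplier(method)
    if (!is.finite(multiplier) || multiplier <= 0) {
        stop("noiseEstimator: multiplier must be positive ",
            "(a zero multiplier would flag every sample)")
    }
    st <- list(method = method, fsHz = fsHz,
        windowLen = as.integer(round(windowMs / 1000 * fsHz)),
        multiplier = multiplier, k = 0L, valid = FALSE,
        pos = NA_real_, neg = NA_real_)
    st <- switch(method,
        bandflt = c(st, list(initWindows = 300L, rmsBuffer = numeric())),
        adabandflt = c(st, list(refresh = 100L, rmsBuffer = numeric(),
            noiseEst = NA_real_)),
        limada = c(st, list(initClean = 100L, ratioLimit = ratioLimit,
            nonzeroEps = nonzeroEps, initValues = numeric(),
            cleanCount = 0L, noiseEst = NA_real_)),
        adaflt = c(st, list(initWindows = 128L, refreshCount = 128L,
            decimation = 10L, postInitIndex = 0L,
            maxBuffer = numeric(), minBuffer = numeric(),
            noiseEstP = NA_real_, noiseEstN = NA_real_)),
        adaflt128 = c(st, list(initWindows = 128L, refreshCount = 128L,
            decimation = 1L, postInitIndex = 0L,
            maxBuffer = numeric(), minBuffer = numeric(),
            noiseEstP = NA_real_, noiseEstN = NA_real_))
    )
    structure(st, class = "NoiseEstimatorState")
}

#' Limada clean-window test
#'
#' A window is "clean" (spike-free and not blanked) when the ratio of
#' its 2nd to its 30th voltage percentile is below \code{ratioLimit}
#' and |V.30| is significantly non-zero. Percentiles are taken on the
#' signed voltages (both are negative for zero-mean noise); a window
#' with V.30 = 0 fails before any division.
#'
#' @param window numeric vector of voltages.
#' @param ratioLimit maximum V.02 / V.30 ratio for a clean window.
#' @param nonzeroEps minimum |V.30| (microvolts).
#' @return list with \code{clean}, \code{v02}, \code{v30}.
#' @export
limadaIsClean <- function(window, ratioLimit = 5, nonzeroEps = 1e-3) {
    v02 <- hwPercentile(window, 2)
    v30 <- hwPercentile(window, 30)
    clean <- abs(v30) > nonzeroEps && (v02 / v30) < ratioLimit
    list(clean = clean, v02 = v02, v30 = v30)
}

#' Form a ThresholdPair from noise estimates
#'
#' Symmetric form: a single non-negative estimate gives
#' \code{(+m * est, -m * est)}. Asymmetric form (the adaflt variants):
#' a positive estimate and a (negative) negative estimate give
#' \code{(m * estP, m * estN)}.
#'
#' @param est non-negative noise estimate (symmetric case).
#' @param estP,estN positive/negative estimates (asymmetric case; pass
#'   instead of \code{est}).
#' @param multiplier positive threshold multiple.
#' @return list with \code{pos}, \code{neg}, \code{valid = TRUE}.
#' @export
thresholdsFromEstimate <- function(est = NULL, multiplier,
        estP = NULL, estN = NULL) {
    if (!is.finite(multiplier) || multiplier <= 0) {
        stop("thresholdsFromEstimate: multiplier must be positive")
    }
    if (!is.null(est)) {
        if (est < 0) stop("thresholdsFromEstimate: negative estimate")
        return(list(pos = multiplier * est, neg = -multiplier * est,
            valid = TRUE))
    }
    list(pos = multiplier * estP, neg = multiplier * estN, valid = TRUE)
}

currentThreshold <- function(st) {
    list(pos = st$pos, neg = st$neg, valid = st$valid)
}

#' Advance a streaming noise estimator by one window
#'
#' @param state a \code{NoiseEstimatorState} from [noiseEstimator()].
#' @param window numeric vector of \code{state$windowLen} samples.
#' @return list with the updated \code{state} and \code{threshold}
#'   (elements \code{pos}, \code{neg}, \code{valid}).
#' @export
processWindow <- function(state, window) {
    if (length(window) != state$windowLen) {
        stop("processWindow: window must have ", state$windowLen, " samples")
    }
    state$k <- state$k + 1L
    state <- switch(state$method,
        bandflt = stepBandFlt(state, window),
        limada = stepLimada(state, window),
        adaflt = stepAdaFlt(state, window),
        adaflt128 = stepAdaFlt(state, window),
        adabandflt = stepAdaBandFlt(state, window))
    list(state = state, threshold = currentThreshold(state))
}

stepBandFlt <- function(st, window) {
    if (st$valid) return(st)  # threshold fixed once initialized
    st$rmsBuffer <- c(st$rmsBuffer, windowRMS(window))
    if (length(st$rmsBuffer) == st$initWindows) {
        est <- hwPercentile(st$rmsBuffer, 25)
        th <- thresholdsFromEstimate(est, st$multiplier)
        st$pos <- th$pos
        st$neg <- th$neg
        st$valid <- TRUE
        st$noiseEst <- est
    }
    st
}

stepAdaBandFlt <- function(st, window) {
    st$rmsBuffer <- c(st$rmsBuffer, windowRMS(window))
    if (length(st$rmsBuffer) == st$refresh) {
        n25 <- hwPercentile(st$rmsBuffer, 25)
        st$noiseEst <- if (!st$valid) n25
            else 0.8 * st$noiseEst + 0.2 * n25
        th <- thresholdsFromEstimate(st$noiseEst, st$multiplier)
        st$pos <- th$pos
        st$neg <- th$neg
        st$valid <- TRUE
        st$rmsBuffer <- numeric()
    }
    st
}

stepLimada <- function(st, window) {
    chk <- limadaIsClean(window, st$ratioLimit, st$nonzeroEps)
    if (!chk$clean) return(st)  # dirty windows leave the state untouched
    st$cleanCount <- st$cleanCount + 1L
    if (!st$valid) {
        st$initValues <- c(st$initValues, abs(chk$v02))
        if (length(st$initValues) == st$initClean) {
            # initialization: mean of the collected |V.02| values
            st$noiseEst <- mean(st$initValues)
            st$valid <- TRUE
        }
    } else {
        st$noiseEst <- 0.99 * st$noiseEst + 0.01 * abs(chk$v02)
    }
    if (st$valid) {
        th <- thresholdsFromEstimate(st$noiseEst, st$multiplier)
        st$pos <- th$pos
        st$neg <- th$neg
    }
    st
}

stepAdaFlt <- function(st, window) {
    if (!st$valid) {
        # initialization consumes every window
        st$maxBuffer <- c(st$maxBuffer, max(window))
        st$minBuffer <- c(st$minBuffer, min(window))
        if (length(st$maxBuffer) == st$initWindows) {
            st$noiseEstP <- hwPercentile(st$maxBuffer, 40)
            st$noiseEstN <- hwPercentile(st$minBuffer, 40)
            th <- thresholdsFromEstimate(multiplier = st$multiplier,
                estP = st$noiseEstP, estN = st$noiseEstN)
            st$pos <- th$pos
            st$neg <- th$neg
            st$valid <- TRUE
            st$maxBuffer <- numeric()
            st$minBuffer <- numeric()
        }
        return(st)
    }
    # running: retain one window in `decimation`, counted from the end
    # of initialization
    st$postInitIndex <- st$postInitIndex + 1L
    if (st$postInitIndex %% st$decimation != 0L) return(st)
    st$maxBuffer <- c(st$maxBuffer, max(window))
    st$minBuffer <- c(st$minBuffer, min(window))
    if (length(st$maxBuffer) == st$refreshCount) {
        m4p <- hwPercentile(st$maxBuffer, 40)
        m4n <- hwPercentile(st$minBuffer, 40)
        st$noiseEstP <- 0.9 * st$noiseEstP + 0.1 * m4p
        st$noiseEstN <- 0.9 * st$noiseEstN + 0.1 * m4n
        th <- thresholdsFromEstimate(multiplier = st$multiplier,
            estP = st$noiseEstP, estN = st$noiseEstN)
        st$pos <- th$pos
        st$neg <- th$neg
        st$maxBuffer <- numeric()
        st$minBuffer <- numeric()
    }
    st
}

#' Estimate per-window detection thresholds over a whole trace
#'
#' Runs one of the five streaming estimators over the (filtered) trace,
#' window by window, and records the thresholds in force at each window.
#'
#' @param x a (band-pass filtered) [Recording-class].
#' @param method estimator name; see [noiseEstimator()].
#' @param ... further arguments to [noiseEstimator()] (e.g.
#'   \code{multiplier}).
#' @return a [ThresholdTrace-class].
#' @examples
#' rec <- Recording(rnorm(25000 * 2), 25000)
#' tt <- estimateThresholds(rec, "adabandflt")
#' @rdname estimateThresholds
#' @export
setMethod("estimateThresholds", "Recording",
    function(x, method = c("adabandflt", "bandflt", "limada", "adaflt",
            "adaflt128"), ...) {
        method <- match.arg(method)
        st <- noiseEstimator(method, samplingRate(x), ...)
        sw <- splitWindows(x, windowMs = 1000 * st$windowLen / samplingRate(x))
        nw <- length(sw$windows)
        pos <- neg <- rep(NA_real_, nw)
        valid <- logical(nw)
        for (i in seq_len(nw)) {
            out <- processWindow(st, sw$windows[[i]])
            st <- out$state
            pos[i] <- out$threshold$pos
            neg[i] <- out$threshold$neg
            valid[i] <- out$threshold$valid
        }
        new("ThresholdTrace", pos = pos, neg = neg, valid = valid,
            windowLen = st$windowLen, fsHz = samplingRate(x),
            method = method, multiplier = st$multiplier)
    })

#' Export a ThresholdTrace as a data.frame
#'
#' One row per window: index, start time, thresholds and validity;
#' suitable for CSV export and plotting.
#'
#' @param x a [ThresholdTrace-class].
#' @param ... ignored.
#' @return data.frame with columns \code{window_index, t_s, pos_uv,
#'   neg_uv, valid}.
#' @export
#' @method as.data.frame ThresholdTrace
as.data.frame.ThresholdTrace <- function(x, ...) {
    nw <- length(x@pos)
    data.frame(window_index = seq_len(nw),
        t_s = (seq_len(nw) - 1L) * x@windowLen / x@fsHz,
        pos_uv = x@pos, neg_uv = x@neg, valid = x@valid)
}
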