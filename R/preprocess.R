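## Band-pass filtering and the windowing primitives shared by every
## noise estimator.

#' Band-pass filter a recording
#'
#' Butterworth band-pass filtering (default 2nd order, 150-2500 Hz),
#' applied causally in a single pass, matching a streaming/hardware
#' signal path. An optional zero-phase mode (forward-backward) is
#' available but off by default.
#'
#' @param x a [Recording-class].
#' @param lowHz,highHz passband edges in Hz; must satisfy
#'   \code{0 < lowHz < highHz < fs/2}.
#' @param order Butterworth order (per band edge).
#' @param zeroPhase if TRUE, filter forward and backward (non-causal).
#' @return a filtered [Recording-class] of the same length and rate.
#' @examples
#' rec <- Recording(sin(2 * pi * 1000 * (0:9999) / 25000), 25000)
#' filt <- bandpassFilter(rec)
#' @rdname bandpassFilter
#' @export
setMethod("bandpassFilter", "Recording",
    function(x, lowHz = 150, highHz = 2500, order = 2, zeroPhase = FALSE) {
        fs <- samplingRate(x)
        if (!(lowHz > 0 && lowHz < highHz && highHz < fs / 2)) {
            stop("bandpassFilter: need 0 < lowHz < highHz < fs/2")
        }
        b <- signal::butter(order, c(lowHz, highHz) / (fs / 2), type = "pass")
        y <- if (zeroPhase) {
            as.numeric(signal::filtfilt(b, samples(x)))
        } else {
            as.numeric(signal::filter(b, samples(x)))
        }
        initialize(x, samples = y)
    })

#' @rdname bandpassFilter
#' @export
setMethod("bandpassFilter", "numeric",
    function(x, lowHz = 150, highHz = 2500, order = 2, zeroPhase = FALSE) {
        stop("bandpassFilter needs a Recording (the sampling rate matters); ",
            "wrap the vector with Recording(x, fsHz)")
    })

#' Split a trace into contiguous analysis windows
#'
#' Non-overlapping windows of \code{windowMs} (default 10 ms), in order;
#' a trailing partial window is discarded.
#'
#' @param x a [Recording-class] or numeric vector.
#' @param windowMs window length in milliseconds.
#' @param fsHz sampling rate (required when \code{x} is a plain vector).
#' @return list with \code{windows} (a list of numeric vectors),
#'   \code{windowLen} (samples) and \code{starts} (1-based start sample
#'   of each window).
#' @export
splitWindows <- function(x, windowMs = 10, fsHz = NULL) {
    if (is(x, "Recording")) {
        fsHz <- samplingRate(x)
        x <- samples(x)
    }
    if (is.null(fsHz)) stop("splitWindows: fsHz required for plain vectors")
    wl <- as.integer(round(windowMs / 1000 * fsHz))
    if (wl < 1L) stop("splitWindows: window shorter than one sample")
    nw <- length(x) %/% wl
    starts <- (seq_len(nw) - 1L) * wl + 1L
    wins <- lapply(starts, function(s) x[s:(s + wl - 1L)])
    list(windows = wins, windowLen = wl, starts = starts)
}
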