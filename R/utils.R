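## Internal helpers shared across modules.

## Evaluate expr with a temporary RNG seed, restoring the caller's RNG
## state afterwards so package functions do not disturb the session.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

#' Root mean square of a window
#'
#' @param window numeric vector (microvolts).
#' @return sqrt(mean(window^2)).
#' @examples
#' windowRMS(c(3, -4)) # sqrt(12.5)
#' @export
windowRMS <- function(window) {
    if (length(window) == 0L) stop("windowRMS: empty window")
    sqrt(mean(window^2))
}

#' Hardware-convention percentile
#'
#' Selects the k-th percentile of a vector by the index rule used in the
#' threshold hardware: the 1-based sorted index is
#' \code{floor(0.5 + n * k / 100)}, clamped to \code{[1, n]}. With
#' n = 100 and k = 25 this selects the 25th sorted element. The same
#' convention is used everywhere a percentile appears (25th of window
#' RMS values, 2nd/30th of window voltages, 40th of window extrema).
#'
#' @param x numeric vector (sorted internally).
#' @param k percentile in (0, 100).
#' @return the selected element of \code{sort(x)}.
#' @examples
#' hwPercentile(1:100, 25) # 25
#' @export
hwPercentile <- function(x, k) {
    n <- length(x)
    if (n == 0L) stop("hwPercentile: empty vector")
    if (!is.finite(k) || k <= 0 || k >= 100) {
        stop("hwPercentile: k must lie in (0, 100)")
    }
    idx <- hwPercentileIndex(n, k)
    sort(x)[idx]
}

#' @rdname hwPercentile
#' @param n vector length.
#' @return \code{hwPercentileIndex()}: the 1-based index selected for a
#'   sorted vector of length \code{n}.
#' @export
hwPercentileIndex <- function(n, k) {
    idx <- floor(0.5 + n * k / 100)
    min(max(idx, 1L), n)
}

## Plateau-aware local extrema of a vector. Returns the earliest index
## of each maximal run of equal values that rises before and falls
## after (local maxima of `x`; call with -x for minima). Endpoints are
## not peaks.
localMaxima <- function(x) {
    n <- length(x)
    if (n < 3L) return(integer())
    d <- diff(x)
    # collapse plateaus: indices where slope changes from + to - across
    # a (possibly empty) run of zeros
    nz <- which(d != 0)
    if (length(nz) < 2L) return(integer())
    s <- sign(d[nz])
    rise <- which(s[-length(s)] > 0 & s[-1] < 0)
    if (length(rise) == 0L) return(integer())
    # peak starts right after the rising step
    nz[rise] + 1L
}
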