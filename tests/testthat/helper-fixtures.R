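# Shared fixtures, built in code.

FS <- 25000

# A short simulation for pipeline-level tests (full 60 s runs live in
# the acceptance suite).
shortSim <- function(seed = 11, durationSec = 20, nEvents = 200L, ...) {
    simulateRecording(simulationConfig(durationSec = durationSec,
        nEvents = nEvents, ...), seed = seed)
}

# Feed a sequence of windows through a streaming estimator, returning
# the final state and the threshold after each window.
feedWindows <- function(state, windows) {
    th <- vector("list", length(windows))
    for (i in seq_along(windows)) {
        out <- processWindow(state, windows[[i]])
        state <- out$state
        th[[i]] <- out$threshold
    }
    list(state = state, thresholds = th)
}

# n copies of one window.
rep_windows <- function(window, n) rep(list(window), n)

# A window of length 250 whose 2nd/30th voltage percentiles (hardware
# convention: sorted indices 5 and 75) are exactly v02 and v30.
windowWithPercentiles <- function(v02, v30, n = 250) {
    stopifnot(v02 <= v30)
    c(rep(v02, 5), rep(v30, 70), rep(abs(v30) + 1, n - 75))
}

# A triangular bump of the given peak inserted at `apex` (1-based) in a
# zero trace.
addTriangle <- function(trace, apex, peak, halfWidth = 10) {
    i <- seq_along(trace)
    trace + peak * pmax(0, 1 - abs(i - apex) / halfWidth)
}

# Direct evaluation of the partition criterion for a labelled score
# matrix: every cluster pair's centroid distance exceeds the sum of
# the two cluster radii.
criterionHolds <- function(scores, labels) {
    ks <- sort(unique(labels))
    cen <- t(vapply(ks, function(i)
        colMeans(scores[labels == i, , drop = FALSE]),
        numeric(ncol(scores))))
    rad <- vapply(seq_along(ks), function(i) {
        p <- scores[labels == ks[i], , drop = FALSE]
        sqrt(max(rowSums((p - matrix(cen[i, ], nrow(p), ncol(p),
            byrow = TRUE))^2)))
    }, numeric(1))
    for (i in seq_along(ks)) {
        for (j in seq_along(ks)) {
            if (i >= j) next
            if (!(rad[i] + rad[j] < sqrt(sum((cen[i, ] - cen[j, ])^2)))) {
                return(FALSE)
            }
        }
    }
    TRUE
}
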