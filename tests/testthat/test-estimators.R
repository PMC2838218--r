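# The five streaming noise estimators: update equations, clean-window
# test, initialization behaviour and streaming equivalence.

test_that("bandflt fixes a symmetric threshold after 300 windows", {
    st <- noiseEstimator("bandflt", FS)
    win <- rep(3, st$windowLen)  # constant window: RMS = 3
    out <- feedWindows(st, rep_windows(win, 299))
    expect_false(out$thresholds[[299]]$valid)
    out <- feedWindows(out$state, rep_windows(win, 1))
    th <- out$thresholds[[1]]
    expect_true(th$valid)
    expect_equal(th$pos, 4 * 3)  # multiplier x 25th pct of equal RMS
    expect_equal(th$neg, -12)
    # fixed thereafter, whatever comes in
    out2 <- feedWindows(out$state, rep_windows(rep(50, st$windowLen), 40))
    expect_equal(out2$thresholds[[40]]$pos, 12)
})

test_that("bandflt noise esteem on unit Gaussian windows sits just below 1", {
    # Monte-Carlo: the 25th percentile of the RMS sampling distribution
    # of 250-sample N(0,1) windows lies in (0.95, 1.00)
    set.seed(14)
    st <- noiseEstimator("bandflt", FS)
    wins <- lapply(1:300, function(i) rnorm(250))
    out <- feedWindows(st, wins)
    est <- out$thresholds[[300]]$pos / 4
    expect_gt(est, 0.95)
    expect_lt(est, 1.00)
})

test_that("the clean-window test accepts noise and rejects spikes and blanks", {
    # standard-normal quantile oracle: V.02/V.30 ~ 2.05/0.52 ~ 4 < 5
    set.seed(1)
    frac <- mean(replicate(200, limadaIsClean(rnorm(250))$clean))
    expect_gt(frac, 0.8)

    chk <- limadaIsClean(windowWithPercentiles(-2.05, -0.52))
    expect_true(chk$clean)
    expect_equal(chk$v02, -2.05)
    expect_equal(chk$v30, -0.52)

    # a window with a large negative spike: ratio far above 5
    set.seed(2)
    spiky <- c(rnorm(240), rep(-100, 10))
    expect_false(limadaIsClean(spiky)$clean)

    # blanked data: V.30 = 0 fails the non-zero test before division
    expect_false(limadaIsClean(numeric(250))$clean)
})

test_that("limada applies its smoother only on clean windows", {
    st <- noiseEstimator("limada", FS)
    st$valid <- TRUE
    st$noiseEst <- 2.0
    clean <- windowWithPercentiles(-3, -1)  # |V.02| = 3, ratio 3
    out <- feedWindows(st, rep_windows(clean, 1))
    expect_equal(out$state$noiseEst, 0.99 * 2.0 + 0.01 * 3.0)  # 2.01
    expect_equal(out$thresholds[[1]]$pos, 4 * 2.01)

    # a dirty window leaves estimate and thresholds untouched
    dirty <- c(rnorm(240), rep(-100, 10))
    out2 <- feedWindows(out$state, rep_windows(dirty, 5))
    expect_equal(out2$state$noiseEst, 2.01)
    expect_equal(out2$thresholds[[5]]$pos, 4 * 2.01)
})

test_that("limada initializes from the mean of 100 clean |V.02| values", {
    st <- noiseEstimator("limada", FS)
    clean <- windowWithPercentiles(-2.5, -1)
    out <- feedWindows(st, rep_windows(clean, 99))
    expect_false(out$thresholds[[99]]$valid)
    out <- feedWindows(out$state, rep_windows(clean, 1))
    expect_true(out$thresholds[[1]]$valid)
    expect_equal(out$state$noiseEst, 2.5)  # mean of 100 identical values
    expect_equal(out$thresholds[[1]]$pos, 10)
})

test_that("adaflt refreshes from 40th-percentile window extrema", {
    st <- noiseEstimator("adaflt128", FS)
    st$valid <- TRUE
    st$noiseEstP <- 10
    st$noiseEstN <- -10
    win <- rep(c(20, -20), st$windowLen / 2)
    out <- feedWindows(st, rep_windows(win, 128))
    # M.4 = 20, m.4 = -20: one refresh of the exponential smoother
    expect_equal(out$state$noiseEstP, 0.9 * 10 + 0.1 * 20)  # 11
    expect_equal(out$state$noiseEstN, 0.9 * -10 + 0.1 * -20)
    expect_equal(out$thresholds[[128]]$pos, 2 * 11)
    expect_equal(out$thresholds[[128]]$neg, 2 * -11)
})

test_that("adaflt thresholds are near-symmetric for sign-symmetric noise", {
    set.seed(8)
    st <- noiseEstimator("adaflt", FS)
    out <- feedWindows(st, lapply(1:128, function(i) rnorm(250)))
    expect_true(out$thresholds[[128]]$valid)
    expect_equal(out$state$noiseEstP, -out$state$noiseEstN,
        tolerance = 0.15)
})

test_that("adaflt128 adapts to a noise step faster than adaflt", {
    mkwin <- function(a) rep(c(a, -a), 125)
    stepTo2After <- function(method, nRaw) {
        st <- noiseEstimator(method, FS)
        st <- feedWindows(st, rep_windows(mkwin(1), 128))$state  # init: est = 1
        feedWindows(st, rep_windows(mkwin(2), nRaw))$state$noiseEstP
    }
    after1280 <- c(adaflt = stepTo2After("adaflt", 1280),
        adaflt128 = stepTo2After("adaflt128", 1280))
    # adaflt128 refreshed 10 times, adaflt once
    expect_equal(after1280[["adaflt"]], 0.9 * 1 + 0.1 * 2)
    expect_equal(after1280[["adaflt128"]], 2 + (1 - 2) * 0.9^10,
        tolerance = 1e-12)
    expect_gt(after1280[["adaflt128"]], after1280[["adaflt"]])
})

test_that("adabandflt initializes at 100 windows and refreshes by Eq-4 smoothing", {
    st <- noiseEstimator("adabandflt", FS)
    st$valid <- TRUE
    st$noiseEst <- 1.0
    win <- rep(1.5, st$windowLen)  # RMS = 1.5 for every window
    out <- feedWindows(st, rep_windows(win, 100))
    expect_equal(out$state$noiseEst, 0.8 * 1.0 + 0.2 * 1.5)  # 1.1
    expect_equal(out$thresholds[[100]]$pos, 4 * 1.1)

    # initialization from scratch: 25th percentile of the first 100 RMS
    st2 <- noiseEstimator("adabandflt", FS)
    out2 <- feedWindows(st2, rep_windows(win, 99))
    expect_false(out2$thresholds[[99]]$valid)
    out2 <- feedWindows(out2$state, rep_windows(win, 1))
    expect_true(out2$thresholds[[1]]$valid)
    expect_equal(out2$state$noiseEst, 1.5)
})

test_that("the update equations follow their exponential closed forms", {
    # after m constant-input refreshes: est_m = c + (init - c) * lambda^m
    m <- 25

    # limada: lambda 0.99, c = 3
    st <- noiseEstimator("limada", FS)
    st$valid <- TRUE
    st$noiseEst <- 2
    st <- feedWindows(st, rep_windows(windowWithPercentiles(-3, -1), m))$state
    expect_equal(st$noiseEst, 3 + (2 - 3) * 0.99^m, tolerance = 1e-12)

    # adabandflt: lambda 0.8, c = 1.5, one refresh per 100 windows
    st <- noiseEstimator("adabandflt", FS)
    st$valid <- TRUE
    st$noiseEst <- 1
    st <- feedWindows(st, rep_windows(rep(1.5, st$windowLen), 100 * m))$state
    expect_equal(st$noiseEst, 1.5 + (1 - 1.5) * 0.8^m, tolerance = 1e-12)

    # adaflt128: lambda 0.9, c = 2 (window extrema +/-2), refresh per 128
    st <- noiseEstimator("adaflt128", FS)
    st$valid <- TRUE
    st$noiseEstP <- 1
    st$noiseEstN <- -1
    st <- feedWindows(st, rep_windows(rep(c(2, -2), 125), 128 * m))$state
    expect_equal(st$noiseEstP, 2 + (1 - 2) * 0.9^m, tolerance = 1e-12)
    expect_equal(st$noiseEstN, -2 + (-1 + 2) * 0.9^m, tolerance = 1e-12)

    # bandflt has no refresh: after initialization the residual never
    # decays (fixed threshold), which is the 0-smoother limit
})

test_that("thresholdsFromEstimate forms symmetric and asymmetric pairs", {
    th <- thresholdsFromEstimate(2.5, multiplier = 4)
    expect_equal(c(th$pos, th$neg), c(10, -10))
    th2 <- thresholdsFromEstimate(multiplier = 2, estP = 3, estN = -2)
    expect_equal(c(th2$pos, th2$neg), c(6, -4))
    expect_error(thresholdsFromEstimate(-1, multiplier = 4), "negative")
    expect_error(noiseEstimator("bandflt", FS, multiplier = 0), "positive")
})

test_that("all five estimators put thresholds above the noise RMS", {
    set.seed(77)
    rec <- Recording(rnorm(FS * 6, sd = 2), FS)  # 6 s of sd-2 noise
    for (m in c("bandflt", "limada", "adaflt", "adaflt128", "adabandflt")) {
        tt <- estimateThresholds(rec, m)
        expect_true(any(tt@valid), info = m)
        last <- max(which(tt@valid))
        expect_gt(tt@pos[last], 2)  # above the noise RMS
        expect_lt(tt@neg[last], -2)
    }
})

test_that("window-by-window streaming equals the whole-trace run", {
    set.seed(55)
    rec <- Recording(rnorm(FS * 5), FS)
    sw <- splitWindows(rec)
    for (m in c("bandflt", "limada", "adaflt128", "adabandflt")) {
        tt <- estimateThresholds(rec, m)
        st <- noiseEstimator(m, FS)
        out <- feedWindows(st, sw$windows)
        pos <- vapply(out$thresholds, function(t) t$pos, numeric(1))
        valid <- vapply(out$thresholds, function(t) t$valid, logical(1))
        expect_equal(pos, tt@pos, info = m)
        expect_identical(valid, tt@valid, info = m)
    }
})
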