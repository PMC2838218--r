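# Synthetic signal generator: templates, event placement, noise, SNR.

test_that("triangle templates have the documented geometry", {
    tpl <- makeTriangleTemplate(100, "+", 20)
    expect_length(tpl$samples, 20)
    expect_equal(max(tpl$samples), 100)
    expect_equal(which.max(tpl$samples), 11)  # apex at the centre sample
    expect_equal(tpl$peak_offset, 11)

    neg <- makeTriangleTemplate(40, "-", 20)
    expect_equal(min(neg$samples), -40)
    expect_equal(max(neg$samples), 0)

    # additive inverse: opposite polarities cancel exactly
    expect_equal(makeTriangleTemplate(63, "+", 21)$samples +
        makeTriangleTemplate(63, "-", 21)$samples, rep(0, 21))

    expect_error(makeTriangleTemplate(-5, "+"), "positive")
    expect_error(makeTriangleTemplate(10, "+", 2), "3 samples")
})

test_that("complex templates are the direct sum of shifted components", {
    base <- makeTriangleTemplate(100, "+", 20)
    cx <- makeComplexTemplate(base, 10, "+")
    expect_length(cx$samples, 30)
    # oracle: direct summation of the shifted vectors
    ref <- c(base$samples, numeric(10)) + c(numeric(10), base$samples)
    expect_equal(cx$samples, ref)

    # a wider shift leaves two distinct local maxima with a dip between
    cx2 <- makeComplexTemplate(base, 14, "+")
    apexes <- which(diff(sign(diff(cx2$samples))) < 0) + 1L
    expect_gte(length(apexes), 2)

    # apexes made to coincide double the amplitude (superposition);
    # shift 0 is disallowed, so check via the underlying sum
    expect_equal(max(base$samples + base$samples), 200)

    # biphasic: one maximum, one minimum, of opposite sign
    bi <- makeComplexTemplate(makeTriangleTemplate(70, "+", 20), 10, "-")
    expect_equal(max(bi$samples), 70)
    expect_equal(min(bi$samples), -70)
    expect_equal(bi$peak_offset, 11)  # earliest of the tied |peaks|

    expect_error(makeComplexTemplate(base, 20, "+"), "overlap")
    expect_error(makeComplexTemplate(base, 0, "+"), "overlap")
})

test_that("clean signal has n_events ground-truth rows with the minimum separation", {
    cfg <- simulationConfig(durationSec = 10, nEvents = 100L, seed = 5)
    out <- generateCleanSignal(cfg)
    gt <- out$groundTruth
    expect_identical(nrow(gt), 100L)
    expect_false(is.unsorted(gt$event_index))
    # brute-force scan of the emitted table
    minSep <- round(cfg$min_separation_ms / 1000 * cfg$fs_hz)
    expect_true(all(diff(gt$event_index) >= minSep))
    # peaks are where the table says they are
    tr <- samples(out$recording)
    expect_true(all(abs(tr[gt$event_index]) > 0))

    # empty case
    empty <- generateCleanSignal(simulationConfig(durationSec = 1,
        nEvents = 0L, seed = 1))
    expect_identical(nrow(empty$groundTruth), 0L)
    expect_true(all(samples(empty$recording) == 0))

    # infeasible packing
    expect_error(simulationConfig(durationSec = 1, nEvents = 500L,
        minSeparationMs = 10), "infeasible")
})

test_that("ground-truth count equals n_events over random feasible configs", {
    set.seed(99)
    for (i in 1:5) {
        ne <- sample(20:150, 1)
        cfg <- simulationConfig(durationSec = 8, nEvents = ne,
            seed = sample.int(1e6, 1))
        expect_identical(nrow(generateCleanSignal(cfg)$groundTruth),
            as.integer(ne))
    }
})

test_that("band-limited noise is unit-RMS, reproducible and band-limited", {
    nz <- generateBandlimitedNoise(2^17, FS, seed = 7)
    expect_equal(windowRMS(nz), 1, tolerance = 1e-9)
    expect_identical(nz, generateBandlimitedNoise(2^17, FS, seed = 7))
    expect_false(identical(nz,
        generateBandlimitedNoise(2^17, FS, seed = 8)))

    # periodogram oracle: power outside the band well below the
    # passband plateau (2nd-order Butterworth rolloff gives >= 12 dB
    # one octave out)
    sp <- stats::spec.pgram(stats::ts(nz, frequency = FS), spans = 51,
        plot = FALSE, taper = 0)
    passDb <- mean(10 * log10(sp$spec[sp$freq > 500 & sp$freq < 1500]))
    lowDb <- mean(10 * log10(sp$spec[sp$freq < 75]))
    highDb <- mean(10 * log10(sp$spec[sp$freq > 10000]))
    expect_gt(passDb - lowDb, 12)
    expect_gt(passDb - highDb, 12)

    expect_error(generateBandlimitedNoise(1000, FS, c(150, 13000)),
        "fs/2")
})

test_that("mixing hits the requested SNR exactly and round-trips", {
    clean <- Recording(addTriangle(numeric(5000), 2500, 80), FS)
    noise <- generateBandlimitedNoise(5000, FS, seed = 3)

    m0 <- mixAtSNR(clean, noise, 0)
    expect_equal(windowRMS(m0$scaledNoise), windowRMS(samples(clean)),
        tolerance = 1e-12)
    m20 <- mixAtSNR(clean, noise, 20)
    expect_equal(windowRMS(m20$scaledNoise),
        windowRMS(samples(clean)) / 10, tolerance = 1e-12)

    for (snr in c(-3, 0, 5, 12.5)) {
        m <- mixAtSNR(clean, noise, snr)
        expect_equal(measureSNR(clean, m$scaledNoise), snr,
            tolerance = 1e-9)
    }
    expect_error(mixAtSNR(Recording(numeric(100), FS), noise[1:100], 5),
        "zero power")
    expect_equal(measureSNR(samples(clean), samples(clean) / 10), 20)
})

test_that("simulateRecording is seed-deterministic and carries its parts", {
    a <- shortSim(seed = 4, durationSec = 5, nEvents = 40L)
    b <- shortSim(seed = 4, durationSec = 5, nEvents = 40L)
    expect_identical(samples(a), samples(b))
    expect_identical(groundTruth(a), groundTruth(b))
    expect_equal(samples(a), a@clean + a@noiseComponent, tolerance = 1e-12)
    expect_equal(measureSNR(a@clean, a@noiseComponent), 5,
        tolerance = 1e-9)
})

test_that("class frequencies follow the configured mix", {
    sim <- simulateRecording(seed = 21)  # default: 600 events, 5 classes
    counts <- table(groundTruth(sim)$class_id)
    expect_identical(sort(names(counts)), c("A", "B", "C", "D", "E"))
    p <- stats::chisq.test(counts, p = rep(0.2, 5))$p.value
    expect_gt(p, 0.001)
})
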