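# PCA, the agglomerative tree, partition selection, pruning, noise
# flagging and reconstruction.

test_that("PCA behaves on degenerate and structured waveform sets", {
    # identical waveforms: zero variance, all scores at the origin
    w <- matrix(rep(sin(1:50), 10), nrow = 10, byrow = TRUE)
    p <- fitPCA(w)
    expect_true(all(abs(p$scores) < 1e-12))

    # two template classes with small jitter: PC1 separates them
    set.seed(6)
    a <- makeTriangleTemplate(80, "+", 50)$samples
    b <- makeTriangleTemplate(80, "-", 50)$samples
    w2 <- rbind(
        t(replicate(15, a + rnorm(50, sd = 2))),
        t(replicate(15, b + rnorm(50, sd = 2))))
    p2 <- fitPCA(w2)
    # oracle: eigen-decomposition of the covariance
    ev <- eigen(stats::cov(w2))
    expect_equal(abs(p2$rotation[, 1]), abs(ev$vectors[, 1]),
        tolerance = 1e-8)
    s1 <- p2$scores[1:15, 1]
    s2 <- p2$scores[16:30, 1]
    expect_true(max(s2) < min(s1) || max(s1) < min(s2))

    # projection property: score variance cannot exceed total variance
    expect_lte(sum(apply(p2$scores, 2, stats::var)),
        sum(apply(w2, 2, stats::var)) + 1e-9)

    # sign convention: the largest loading of each component is positive
    for (j in 1:2) {
        expect_gt(p2$rotation[which.max(abs(p2$rotation[, j])), j], 0)
    }
    expect_error(fitPCA(w[1, , drop = FALSE]), "at least 2")
})

test_that("the agglomerative tree merges nearest centroids first", {
    # three collinear points: {0, 1} merge before 10 joins
    tr <- buildTree(cbind(c(0, 1, 10), 0))
    expect_equal(sort(-tr$merge[1, ]), c(1, 2))

    # duplicate points merge at height 0
    tr2 <- buildTree(cbind(c(5, 5, 9), 0))
    expect_equal(tr2$height[1], 0)
    expect_equal(sort(-tr2$merge[1, ]), c(1, 2))

    expect_null(buildTree(matrix(1, 1, 2)))
})

test_that("partition selection returns the largest cut meeting the criterion", {
    # one tight blob: no multi-cluster cut passes, fall back to M = 1
    set.seed(40)
    ang <- runif(30, 0, 2 * pi)
    r <- sqrt(runif(30))
    blob <- cbind(r * cos(ang), r * sin(ang))  # uniform disc, radius 1
    m1 <- selectPartition(buildTree(blob), blob)
    expect_identical(m1@k, 1L)

    # two such blobs 10 apart: M = 2, verified against the direct
    # criterion evaluation over all cuts
    blob2 <- rbind(blob, sweep(blob, 2, c(10, 0), "+"))
    tree <- buildTree(blob2)
    m2 <- selectPartition(tree, blob2)
    for (M in 7:2) {
        lab <- stats::cutree(tree, k = M)
        if (criterionHolds(blob2, lab)) {
            expect_identical(m2@k, as.integer(M))
            break
        }
    }
    expect_identical(m2@k, 2L)
    expect_equal(sort(unique(m2@labels)), 1:2)

    # the returned multi-cluster partition always satisfies the criterion
    expect_true(criterionHolds(blob2, m2@labels))

    # a single point yields the trivial partition
    single <- selectPartition(NULL, matrix(c(1, 2), 1, 2))
    expect_identical(single@k, 1L)
})

test_that("pruning rejects small clusters and singletons, without re-merging", {
    set.seed(41)
    sc <- rbind(
        cbind(rnorm(300, 0, .1), rnorm(300, 0, .1)),
        cbind(rnorm(12, 10, .1), rnorm(12, 10, .1)),
        cbind(rnorm(9, 20, .1), rnorm(9, 20, .1)),
        c(40, 40))
    labels <- rep(1:4, c(300, 12, 9, 1))
    model <- new("SpikeSorting", labels = as.integer(labels), k = 4L,
        centroids = matrix(0, 4, 2), dispersions = numeric(4),
        sizes = c(300L, 12L, 9L, 1L), accepted = rep(TRUE, 4),
        isNoise = rep(FALSE, 4), clusterMeans = matrix(numeric(), 0, 0),
        scores = sc, pca = list(), tree = NULL,
        config = sortingConfig())
    pruned <- pruneClusters(model)
    expect_identical(pruned@accepted, c(TRUE, TRUE, FALSE, FALSE))
    # the singleton keeps its own label: excluded, not re-merged
    expect_identical(sum(pruned@labels == 4L), 1L)

    allBig <- pruneClusters(model, sortingConfig(minClusterSize = 1))
    expect_true(all(allBig@accepted))
})

test_that("noise flagging uses a strict 30 uV peak-to-peak rule", {
    mk <- function(pp) {
        w <- numeric(50)
        w[26] <- pp / 2
        w[30] <- -pp / 2
        w
    }
    w <- rbind(
        t(replicate(12, mk(25))),   # cluster 1: pk-pk 25 -> noise
        t(replicate(12, mk(30))),   # cluster 2: exactly 30 -> kept
        t(replicate(12, mk(90))))   # cluster 3: real spikes
    model <- new("SpikeSorting",
        labels = rep(1:3, each = 12L), k = 3L,
        centroids = matrix(0, 3, 2), dispersions = numeric(3),
        sizes = rep(12L, 3), accepted = rep(TRUE, 3),
        isNoise = rep(FALSE, 3), clusterMeans = matrix(numeric(), 0, 0),
        scores = matrix(0, 36, 2), pca = list(), tree = NULL,
        config = sortingConfig())
    flagged <- flagNoiseClusters(model, w)
    expect_identical(flagged@isNoise, c(TRUE, FALSE, FALSE))
})

test_that("reconstruction places cluster means at event positions", {
    # zero accepted events: an all-zero trace
    ev <- data.frame(peak_index = 100L, time_s = 99 / FS, polarity = "+",
        peak_amplitude_uv = 50, validated = TRUE)
    w <- matrix(0, 1, 50)
    w[1, 26] <- 50
    wfs <- new("WaveformSet", waveforms = w, alignmentOffset = 26L,
        fsHz = FS, events = ev, nDropped = 0L)
    none <- new("SpikeSorting", labels = 1L, k = 1L,
        centroids = matrix(0, 1, 2), dispersions = 0,
        sizes = 1L, accepted = FALSE, isNoise = FALSE,
        clusterMeans = w, scores = matrix(0, 1, 2), pca = list(),
        tree = NULL, config = sortingConfig())
    expect_true(all(samples(reconstructSignal(wfs, none, 500)) == 0))

    # a single accepted event reproduces its cluster mean in place
    one <- none
    one@accepted <- TRUE
    rec <- samples(reconstructSignal(wfs, one, 500))
    expect_equal(rec[75:124], w[1, ])
    expect_true(all(rec[-(75:124)] == 0))
})

test_that("sorting labels are deterministic given the input", {
    sim <- shortSim(seed = 77, durationSec = 15, nEvents = 150L)
    filt <- bandpassFilter(sim)
    th <- estimateThresholds(filt, "adabandflt")
    sp <- detectSpikes(filt, th)
    wfs <- extractWaveforms(filt, sp)
    a <- sortSpikes(wfs)
    b <- sortSpikes(wfs)
    expect_identical(a@labels, b@labels)
    expect_identical(a@k, b@k)
    # the chosen multi-cluster partition satisfies the criterion
    if (a@k > 1) expect_true(criterionHolds(a@scores, a@labels))
})
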