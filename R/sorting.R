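## PCA feature extraction and hierarchical classification: centroid-
## linkage tree over the 2-D principal-component scores, partition cut
## chosen by the dispersion-versus-centroid-distance criterion,
## minimum-size pruning, noise-cluster flagging and signal
## reconstruction from cluster mean waveforms.

#' Sorting configuration
#'
#' @param nComponents number of principal components kept (default 2).
#' @param maxClusters largest partition examined (default 7: a likely
#'   maximum of cell bodies per electrode plus one or two noise
#'   sources).
#' @param minClusterSize smallest cluster not rejected (default 10).
#' @param noisePpUv peak-to-peak amplitude (microvolts) below which an
#'   accepted cluster's mean waveform is flagged as noise (default 30;
#'   strict less-than).
#' @return a configuration list.
#' @export
sortingConfig <- function(nComponents = 2L, maxClusters = 7L,
        minClusterSize = 10L, noisePpUv = 30) {
    stopifnot(nComponents >= 1L, maxClusters >= 1L, minClusterSize >= 1L,
        noisePpUv > 0)
    list(n_components = as.integer(nComponents),
        max_clusters = as.integer(maxClusters),
        min_cluster_size = as.integer(minClusterSize),
        noise_pp_uv = noisePpUv)
}

#' Fit PCA on a waveform matrix
#'
#' Mean-centred eigen-decomposition of the waveform covariance; scores
#' for the leading components. For reproducibility each component's
#' largest-magnitude loading is made positive.
#'
#' @param waveforms numeric matrix (N x c) or a [WaveformSet-class].
#' @param nComponents components to keep.
#' @return list with \code{scores} (N x nComponents), \code{rotation},
#'   \code{center}, \code{sdev}.
#' @export
fitPCA <- function(waveforms, nComponents = 2L) {
    if (is(waveforms, "WaveformSet")) waveforms <- waveforms@waveforms
    if (nrow(waveforms) < 2L) stop("fitPCA: need at least 2 waveforms")
    nComponents <- min(nComponents, ncol(waveforms))
    p <- stats::prcomp(waveforms, center = TRUE, scale. = FALSE)
    rot <- p$rotation[, seq_len(nComponents), drop = FALSE]
    sc <- p$x[, seq_len(nComponents), drop = FALSE]
    for (j in seq_len(ncol(rot))) {
        i <- which.max(abs(rot[, j]))
        if (rot[i, j] < 0) {
            rot[, j] <- -rot[, j]
            sc[, j] <- -sc[, j]
        }
    }
    list(scores = sc, rotation = rot, center = p$center,
        sdev = p$sdev[seq_len(nComponents)])
}

#' Agglomerative tree over PCA scores
#'
#' Centroid-linkage agglomeration with Euclidean distances between
#' cluster centroids, from N singletons to one cluster.
#'
#' @param scores numeric matrix (N x d).
#' @return an \code{hclust} object, or NULL for N = 1.
#' @export
buildTree <- function(scores) {
    scores <- as.matrix(scores)
    n <- nrow(scores)
    if (n < 1L) stop("buildTree: no points")
    if (n == 1L) return(NULL)
    # centroid linkage in hclust is defined on squared Euclidean
    # distances; merge heights are then squared centroid distances
    stats::hclust(stats::dist(scores)^2, method = "centroid")
}

clusterStats <- function(scores, labels, k) {
    centroids <- matrix(NA_real_, k, ncol(scores))
    disp <- numeric(k)
    sizes <- integer(k)
    for (i in seq_len(k)) {
        m <- labels == i
        sizes[i] <- sum(m)
        pts <- scores[m, , drop = FALSE]
        centroids[i, ] <- colMeans(pts)
        d2 <- rowSums((pts - matrix(centroids[i, ], nrow(pts),
            ncol(pts), byrow = TRUE))^2)
        # cluster radius: an extent measure, so that splitting a single
        # blob (centroid separation ~1.6 sigma, radius ~2.8 sigma) fails
        # the criterion while genuinely separated groups pass
        disp[i] <- sqrt(max(d2))
    }
    list(centroids = centroids, dispersions = disp, sizes = sizes)
}

## The partition criterion, symmetric form: for every cluster pair the
## centroid distance must exceed the sum of the two dispersions (the
## clusters' extents must not reach each other). The literal one-sided
## form (D_i alone) accepts the split of any single blob -- a rim clump
## has a tiny dispersion and sits about one radius from the remaining
## centroid -- so it never rejects a cut and the criterion would be
## vacuous.
partitionSatisfiesCriterion <- function(centroids, dispersions) {
    k <- nrow(centroids)
    if (k < 2L) return(TRUE)  # vacuous for a single cluster
    for (i in seq_len(k - 1L)) {
        for (j in seq(i + 1L, k)) {
            dij <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
            if (!(dispersions[i] + dispersions[j] < dij)) return(FALSE)
        }
    }
    TRUE
}

#' Choose the partition from the tree
#'
#' Examines cuts from \code{min(maxClusters, N)} clusters downward and
#' returns the first (largest) number of clusters whose partition
#' satisfies the separation criterion: every pair of clusters has a
#' centroid distance larger than the sum of the two dispersions
#' (cluster radii), so no cluster's extent reaches another's.
#' Falls back to a single cluster. Singletons (dispersion 0) may be
#' part of the chosen partition; they are only excluded later by
#' [pruneClusters()].
#'
#' @param tree the \code{hclust} tree from [buildTree()] (or NULL for a
#'   single point).
#' @param scores the N x d score matrix the tree was built on.
#' @param config a list from [sortingConfig()].
#' @return a [SpikeSorting-class] with the partition and per-cluster
#'   statistics; acceptance and noise flags are all TRUE/FALSE defaults
#'   until [pruneClusters()] / [flagNoiseClusters()] run.
#' @export
selectPartition <- function(tree, scores, config = sortingConfig()) {
    scores <- as.matrix(scores)
    n <- nrow(scores)
    if (n == 1L) {
        labels <- 1L
        k <- 1L
    } else {
        k <- 1L
        labels <- rep(1L, n)
        top <- min(config$max_clusters, n)
        for (m in if (top >= 2L) seq(top, 2L) else integer()) {
            lab <- stats::cutree(tree, k = m)
            cs <- clusterStats(scores, lab, m)
            if (partitionSatisfiesCriterion(cs$centroids, cs$dispersions)) {
                labels <- as.integer(lab)
                k <- as.integer(m)
                break
            }
        }
    }
    cs <- clusterStats(scores, labels, k)
    new("SpikeSorting", labels = as.integer(labels), k = k,
        centroids = cs$centroids, dispersions = cs$dispersions,
        sizes = cs$sizes, accepted = rep(TRUE, k),
        isNoise = rep(FALSE, k),
        clusterMeans = matrix(numeric(), 0L, 0L),
        scores = scores, pca = list(), tree = tree,
        config = config)
}

#' Prune small clusters
#'
#' Clusters smaller than the minimum size are marked rejected; a
#' single-element cluster participates in clustering but is excluded
#' here, never re-merged into a neighbour.
#'
#' @param model a [SpikeSorting-class].
#' @param config a list from [sortingConfig()].
#' @return the model with updated \code{accepted} flags.
#' @export
pruneClusters <- function(model, config = model@config) {
    model@accepted <- model@sizes >= config$min_cluster_size
    model
}

#' Flag noise clusters
#'
#' An accepted cluster whose mean waveform has peak-to-peak amplitude
#' strictly below \code{noise_pp_uv} is flagged as noise: it typically
#' collects false-positive detections. Flagged clusters are kept but
#' reported separately.
#'
#' @param model a [SpikeSorting-class].
#' @param waveforms the [WaveformSet-class] (or matrix) that was sorted.
#' @param config a list from [sortingConfig()].
#' @return the model with \code{clusterMeans} and \code{isNoise} filled.
#' @export
flagNoiseClusters <- function(model, waveforms, config = model@config) {
    if (is(waveforms, "WaveformSet")) waveforms <- waveforms@waveforms
    k <- model@k
    means <- matrix(NA_real_, k, ncol(waveforms))
    for (i in seq_len(k)) {
        means[i, ] <- colMeans(waveforms[model@labels == i, , drop = FALSE])
    }
    pp <- apply(means, 1L, function(m) max(m) - min(m))
    model@clusterMeans <- means
    model@isNoise <- model@accepted & pp < config$noise_pp_uv
    model
}

#' Sort spikes: PCA + hierarchical classification
#'
#' Full classification of a [WaveformSet-class]: PCA projection onto the
#' leading components, centroid-linkage tree, partition cut by the
#' dispersion-versus-centroid-distance criterion, minimum-size pruning
#' and noise flagging.
#'
#' @param x a [WaveformSet-class].
#' @param config a list from [sortingConfig()].
#' @return a [SpikeSorting-class].
#' @examples
#' \dontrun{
#' sorting <- sortSpikes(wfs)
#' table(clusterLabels(sorting))
#' }
#' @rdname sortSpikes
#' @export
setMethod("sortSpikes", "WaveformSet", function(x, config = sortingConfig()) {
    if (nrow(x@waveforms) < 2L) stop("sortSpikes: need at least 2 waveforms")
    pca <- fitPCA(x, config$n_components)
    tree <- buildTree(pca$scores)
    model <- selectPartition(tree, pca$scores, config)
    model@pca <- pca[c("rotation", "center", "sdev")]
    model <- pruneClusters(model, config)
    flagNoiseClusters(model, x, config)
})

#' Reconstruct the classified signal
#'
#' Builds a zero trace and adds, at each accepted event's aligned
#' position, its cluster's mean waveform. Noise-flagged clusters are
#' included by default (set \code{excludeNoise = TRUE} to omit them).
#'
#' @param x a [WaveformSet-class] (supplies events and alignment).
#' @param sorting the [SpikeSorting-class] for those waveforms.
#' @param traceLen length of the output trace in samples.
#' @param excludeNoise drop noise-flagged clusters.
#' @return a [Recording-class] with the reconstruction.
#' @rdname reconstructSignal
#' @export
setMethod("reconstructSignal", "WaveformSet",
    function(x, sorting, traceLen, excludeNoise = FALSE) {
        out <- numeric(traceLen)
        cLen <- ncol(x@waveforms)
        pre <- x@alignmentOffset - 1L
        ev <- x@events
        use <- sorting@accepted[sorting@labels]
        if (excludeNoise) use <- use & !sorting@isNoise[sorting@labels]
        for (i in which(use)) {
            m <- sorting@clusterMeans[sorting@labels[i], ]
            s <- ev$peak_index[i] - pre
            span <- s:(s + cLen - 1L)
            ok <- span >= 1L & span <= traceLen
            out[span[ok]] <- out[span[ok]] + m[ok]
        }
        Recording(out, x@fsHz, "reconstruction")
    })
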