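---
title: "meaSpike: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{meaSpike: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaSpike)
```

## The problem

Neurons cultured on microelectrode arrays (MEAs) produce extracellular
action potentials (spikes) of tens of microvolts riding on a comparable
noise floor. Each electrode sees the superimposed activity of several
nearby cells (multi-unit activity), so two tasks arise: *detection* —
finding spike times without prior knowledge of the waveforms — and
*sorting* — assigning the detected waveforms to putative source
neurons. For long, unattended recordings both must be unsupervised,
adaptive (noise floors drift over hours) and cheap enough for a
streaming implementation.

meaSpike implements an amplitude-threshold detector built on five
interchangeable noise-level estimators, a two-part peak validation
rule, peak-aligned waveform extraction, and a PCA + hierarchical
classifier, together with a ground-truthed simulator so the whole
pipeline can be exercised and scored without external data.

## Processing model

All analysis runs on the band-pass filtered trace: a 2nd-order
Butterworth band-pass (150–2500 Hz by default), applied **causally** in
a single pass, matching a streaming signal path. A zero-phase mode
(`zeroPhase = TRUE`) exists for offline exploration but is off by
default, since a causal path is what a hardware or real-time
implementation sees. Estimators consume contiguous, non-overlapping
10 ms windows (250 samples at 25 kHz); a trailing partial window is
discarded.

### The percentile convention

Every percentile in the package (25th of window RMS values, 2nd/30th of
window voltages, 40th of window extrema) uses one index rule on the
sorted vector:

    index = floor(0.5 + n * k / 100), clamped to [1, n]

i.e. the truncated value of `0.5 + n*k/100`, as integer hardware
arithmetic computes it. For n = 100, k = 25 this selects the 25th
sorted element. Truncation (rather than round-half-away-from-zero,
which would select the 26th element from 25.5) was chosen because it is
the convention a fixed-point implementation realizes and it keeps the
25th-of-100 case at index 25; see `hwPercentileIndex()`.

### The five noise estimators

Each estimator maintains a noise-level estimate (µV) and emits
thresholds `±multiplier × estimate` (asymmetric for the extrema-based
variants). Until its initialization completes, its thresholds are
flagged invalid.

| method | estimate | initialization | update | multiplier |
|---|---|---|---|---|
| `bandflt` | 25th pct of window RMS | 300 windows (3 s) | none — fixed | 4 |
| `limada` | smoothed \|V.02\| of clean windows | 100 clean windows | `est ← 0.99·est + 0.01·|V.02|` per clean window | 4 |
| `adaflt` | 40th pct of window maxima / minima | 128 windows | `est ← 0.9·est + 0.1·M.4` per 128 retained windows, retaining 1 window in 10 | 2 |
| `adaflt128` | as `adaflt` | 128 windows | as `adaflt`, retaining every window | 2 |
| `adabandflt` | 25th pct of window RMS | 100 windows (1 s) | `est ← 0.8·est + 0.2·N.25` per 100 windows | 4 |

`limada`'s clean-window test computes the 2nd and 30th voltage
percentiles (V.02, V.30) of each window on the signed values: a window
is clean iff `V.02 / V.30 < 5` and `|V.30|` exceeds `nonzeroEps`
(default 1e-3 µV — the test's only job is to reject blanked data, so
the guard sits below any realistic ADC step). For zero-mean noise both
percentiles are negative and the ratio is about 3.9–4.0, safely below
5; a window containing a spike inflates `|V.02|` and fails. Three
choices here were genuinely open and are worth recording:

* **Limada initialization value.** Defined "after the collection of 100
  clean windows" but not how; we use the mean of the 100 collected
  `|V.02|` values — unbiased and a smooth start for the 0.99/0.01
  smoother.
* **Update on clean windows only.** The clean-window machinery exists
  to keep spikes out of the noise estimate, so the smoother runs only
  on clean windows; dirty windows leave the state untouched.
* **`adabandflt` multiplier.** Only the fixed-threshold estimator's
  multiple (4) is stated; `adabandflt` is its adaptive refinement and
  inherits 4. It is a constructor argument (`multiplier=`) if you
  disagree.

All three smoothers are exponential filters: after m refreshes at a
constant input c, the estimate equals `c + (init − c)·λ^m` with λ ∈
{0.99, 0.9, 0.8}; the test suite asserts these closed forms to 1e-12.

### Detection and the initialization span

At each sample the detector applies the most recent valid threshold
pair (zero-order hold). By default the *first* valid pair is also held
backward over the initialization span, the natural offline convention:
a fixed threshold computed from the first 3 s is applied to the whole
record, and the adaptive estimators lose nothing to their warm-up.
`skipInitial = TRUE` restores the strict streaming behaviour (samples
before initialization are undetectable), which is how a non-reversible
hardware detector would behave. The screening results on the simulated
benchmark (one or zero missed spikes out of 600) are only reproducible
under the offline convention; under the streaming convention every
spike inside the warm-up is lost by construction.

Each contiguous supra-threshold excursion yields one candidate at its
extremum (earliest sample on ties), with the extremum's polarity.

### Peak validation

A candidate is tested in a ±1 ms window: (a) it must be the highest
peak of either polarity (largest absolute value; an equal value at an
earlier sample defeats it), and (b) half its amplitude must exceed
every *other* same-polarity local peak in the window. Competitors in
(b) are plateau-aware local extrema, not raw samples — otherwise a
candidate's own flanks would defeat it. Read literally, the rule
rejects *both* of two comparable same-polarity peaks (e.g. 100 µV and
60 µV, 0.5 ms apart: 50 < 60, and 60 is not the highest); that literal
behaviour is the default, with `keepLarger = TRUE` available to retain
the larger one. Candidates whose window leaves the trace are discarded
and counted, never silently kept.

### Extraction and alignment

Validated events are cut out with a symmetric 2 ms window
(`c = round(0.002·fs)` samples — 50 at 25 kHz) and aligned so the
tallest peak (largest |value|) sits at column `floor(c/2) + 1`
(column 26 of 50). For a validated event the event peak already is the
tallest sample in that window; for unvalidated events the window is
re-centred until stable. Boundary events are dropped and counted.

## Sorting

Waveforms are projected onto the first two principal components
(mean-centred, unscaled PCA; each component's largest-magnitude loading
is made positive so signs are reproducible). Clustering is
agglomerative with centroid linkage on the 2-D scores (`stats::hclust`
on squared Euclidean distances, the metric centroid linkage is defined
for). Working in the score space, not the 50-dimensional waveform
space, matches the classifier's published use and keeps the dispersion
and centroid distances in one scale.

### Choosing the partition

Cuts are examined from `min(maxClusters, N)` clusters downward and the
first (largest) cut whose clusters are pairwise separated is kept:

    D_i + D_j < ||Cm_i − Cm_j||   for every pair i ≠ j

where `Cm_i` is the cluster centroid and the dispersion `D_i` is the
**cluster radius** — the largest member-to-centroid distance
(0 for singletons). Two choices here deserve justification:

* **Dispersion = radius.** With a variance-like dispersion (RMS
  distance) the criterion is vacuous: cutting one isotropic Gaussian
  blob in half gives centroid separation ≈ 1.6σ against an RMS spread
  ≈ 1.2σ, so *any* split of *any* blob passes and the search always
  returns `maxClusters`. An extent measure is needed for the criterion
  to mean anything.
* **Symmetric comparison.** The one-sided form (`D_i` alone against
  every centroid distance) is also vacuous in practice: finer cuts
  isolate small rim clumps whose own dispersion is tiny while they sit
  about one radius away from the remaining centroid, so they always
  pass. The symmetric form — the two extents must not reach each
  other — rejects such splits while accepting genuinely separated
  groups, and makes the intended toy behaviours hold (two tight blobs
  10 apart → 2 clusters; one blob → 1 cluster).

Defaults: `maxClusters = 7` (a plausible maximum of cell bodies in one
electrode's field plus one or two noise sources), `minClusterSize = 10`,
`noisePpUv = 30`.

### Pruning, noise flagging, reconstruction

Clusters smaller than `minClusterSize` are rejected after
classification; singletons participate in the tree and the cut but are
rejected at this final step rather than re-merged, avoiding forced
re-arrangements. An accepted cluster whose mean waveform has
peak-to-peak amplitude strictly below 30 µV is flagged as noise: it
collects the false-positive detections that a deliberately sensitive
detector lets through, and flagging (rather than deleting) it is what
lets a low-specificity detector be corrected after classification.
`reconstructSignal()` rebuilds the trace by stamping each accepted
event's cluster-mean waveform at its aligned position; because the
means come from the causally filtered trace, the like-for-like
comparison target is the filtered clean signal, not the raw one.

## Evaluation

Detections are matched to ground truth by greedy nearest-neighbour
one-to-one pairing within ±1 ms — the tolerance mirrors the validation
window, since no matching rule is published. Paired detections are TP,
unpaired detections FP, unpaired truths FN, and Se, Sp, PPV, NPV follow
the standard screening-test definitions, with zero-denominator ratios
reported as NA with a reason. True negatives need an enumerable
population of "noise peaks"; they are defined only for ground-truthed
data, as the local extrema of the filtered trace outside ±1 ms of any
truth event that no detection claims. This is a documented
reconstruction of an under-specified quantity, not a claim of
equivalence with any published TN denominator. Screening runs on
*unvalidated* detections by default, which is how the estimators are
compared.

`initializationComplexityCrossover()` captures the worst-case
initialization costs of the two preferred estimators: the clean-window
estimator sorts N window voltages for each of 100 clean windows
(O(100·F·N²) with a bubble-sort-style constant F), the adaptive
RMS-percentile estimator sorts 100 window RMS values (O(100²·F)). The
costs cross at N = 10 samples regardless of F — far below any usable
window length, which is why the RMS-percentile estimator wins.

## The simulator

`simulateRecording()` emulates the benchmark recording: 60 s at
25 kHz with 600 events drawn uniformly over five waveform classes —
positive and negative 20-sample triangles (80 µV), a 45 µV positive
triangle, a same-polarity overlapped complex and a biphasic complex
(70 µV) — in white Gaussian noise band-limited to 150–2500 Hz
(2nd-order Butterworth), normalized to unit RMS and scaled so that
`20·log10(RMS_clean/RMS_noise)` equals 5 dB *exactly* (the scaling is
algebraic, not estimated). Event positions are uniform with rejection
to enforce a 5 ms minimum separation; classes are multinomial draws
from `classMix`. Everything is reproducible from one integer seed.

Choices the source conditions leave open, fixed here once:

* **Class amplitudes and shapes.** Only the 40–100 µV peak range, the
  20-sample length and the existence of two overlapped-complex shapes
  are stated; the five classes above span that range and include both
  complex shapes. The same-polarity complex uses a 0.5 ms shift with
  the second component scaled to 0.8: equal amplitudes at a shift equal
  to the apex half-width make the two ramps sum to an exactly flat
  0.4 ms top, leaving the "tallest peak" — the alignment time stamp —
  undefined, and alignment then jitters across the plateau and splits
  the class. A waveform whose peak time is well defined is the
  realistic choice.
* **Event placement.** A 5 ms minimum separation, so every ground-truth
  event is individually resolvable at the ±1 ms matching tolerance.
  The price of this choice is that spike *collisions* never occur:
  no overlap-distorted waveforms, hence no stray outlier clusters, and
  no collision-induced missed detections. On this simulation the
  detector's false negatives are 0 rather than the occasional 1 a
  collision would cause, and the classifier resolves the false-positive
  population into *two* noise clusters (positive and negative peaks,
  well separated in PC space and both flagged by the 30 µV rule)
  instead of one merged cluster plus a collision-artifact singleton.
  Real MUA contains collisions; passing tests here says nothing about
  overlap resolution, which is out of scope.

What the simulation does not emulate: biophysical waveform variety
within a class (class jitter comes only from additive noise), noise
floor drift, electrode artifacts, and correlated multi-channel
structure. Detection and sorting results on it are therefore an upper
bound on real-data performance.

## Numerical conventions and degenerate inputs

* Indices are 1-based; windows are contiguous and non-overlapping;
  ties (equal extrema, equal percentile candidates) resolve to the
  earliest sample.
* All computation is floating-point µV; the squared-domain hardware
  shortcut (comparing squared samples against squared thresholds) is
  not used.
* A zero-power clean signal makes SNR undefined (error); an all-zero
  window fails the clean test via the `nonzeroEps` guard before any
  division; a zero threshold multiplier is rejected as a configuration
  error; empty windows and empty vectors error rather than returning
  NA.
* `fitPCA` requires at least two waveforms; a single-point sorting is
  the trivial one-cluster partition.

## Problem sizes in the test suite

Unit and property tests run on seconds-long simulations (5–20 s,
40–200 events) and hand-built toy traces; the acceptance tests run the
full 60 s benchmark once end to end plus five seeded detection
repeats — small enough to keep the default suite around a minute on
one CPU while still exercising the exact benchmark conditions.

## Known limitations

* No overlap resolution beyond the 50% validation rule; superimposed
  spikes closer than 1 ms are not disentangled.
* Channels are processed independently; there is no cross-channel unit
  merging.
* The hierarchical cut considers at most `maxClusters` partitions of
  one centroid-linkage tree; it cannot recover structure the tree
  never separates.
* True negatives (and hence Sp, NPV) are defined only against ground
  truth and depend on the local-extrema candidate population.
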