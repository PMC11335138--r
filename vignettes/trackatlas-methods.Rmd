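---
title: "Models and methods behind trackatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trackatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackatlas)
```

trackatlas compiles tracking-software exports from a
`condition/repeat/field-of-view` directory tree into one paired
spot-table + track-table dataset and analyses it end to end. This vignette
records the models, conventions and numerical choices the package commits
to — the things a careful user (or a reviewer of a result produced with
it) would want written down.

## The unified dataset

A spot row is one detected object in one frame; a track row is one object
followed over time. The two tables share a `unique_track_id` built as
`"<file stem>::<source track id>"`, which is globally unique provided file
stems are unique across the tree (duplicate stems raise an integrity error
rather than being silently disambiguated). Conventions:

* Frames are 0-based integers; time is `frame * frame_interval` unless the
  export carries an explicit time column.
* Coordinates stay in the source's calibrated units; a pixel-to-length
  conversion is applied only when the column map declares pixel
  coordinates and a pixel size.
* The biological repeat column is named `replicate` (the natural word
  `repeat` is reserved in R and would force quoting throughout user code).
* Untracked spots (spots in no track) are dropped on load, with a count
  reported; tracking is an upstream responsibility.
* 3-D datasets load and compute metrics (z enters all distances), but the
  spatial module refuses them: its estimators and region-of-interest
  geometry are 2-D + time.

## Smoothing and filtering

Smoothing replaces each coordinate by a centred moving average over up to
`window` spots, with *truncated* windows at track ends — no positions are
invented by padding or interpolation. Raw coordinates are kept in
companion `*_raw` columns. One consequence worth knowing: on a perfectly
straight, equally spaced track, the truncated end windows shorten the
first and last smoothed steps, so end-sensitive speed statistics (minimum,
mean) change slightly while collinearity, directionality, and the median
and maximum step speed are preserved. Smoothing is aimed at jittery
centroids (e.g. nuclei) before directionality-type metrics are read.

Filter thresholds mirror the usual phrasing of post-tracking filters:
duration is inclusive (a track "lasting less than" the cutoff is removed,
so exactly-at-cutoff survives), while spot count and total distance are
strict (`> 6 spots` removes a 6-spot track). Filtering is idempotent and
reports kept/removed counts.

## Motility metrics

With positions $p_i$, times $t_i$, steps $v_i = p_{i+1} - p_i$ of length
$\ell_i$: total distance $L = \sum \ell_i$, displacement
$D = |p_{n-1} - p_0|$, directionality $D/L$ (0 when $L = 0$), tortuosity
$L/D$ (NaN when $D = 0$), step speeds $\ell_i / \Delta t_i$, mean
straight-line speed $D/\text{duration}$, linearity of forward progression
(mean straight-line speed over mean speed). Turning angles are unsigned,
$\theta_i = \angle(v_i, v_{i+1}) \in [0, \pi]$ — a magnitude reading that
extends unchanged to 3-D; pairs involving a zero-length step are skipped
(the angle is undefined). The mean directional change rate divides each
$\theta_i$ by its leading step duration $\Delta t_i$. Spatial coverage is
the convex-hull area of the track's positions (0 below three distinct
non-collinear points). `CONFINEMENT_RATIO` is exported as an alias of
directionality: both names circulate for net displacement over path
length, and when a tracking program exports its own value it is imported
as-is rather than recomputed. Gap counts derive from frame jumps: a jump
of $k > 1$ frames is one gap of length $k - 1$.

Degenerate inputs produce defined sentinels instead of errors:
single-spot tracks have zero duration/distances and NaN speeds;
zero-displacement loops have directionality 0 and tortuosity NaN. The
whole engine is validated against an independently written naive
per-track loop to $10^{-9}$ on a thousand random synthetic tracks, and
checked for rigid-motion invariance and the correct behaviour under
coordinate scaling.

## Statistics

Cohen's $d$ uses the pooled sample SD. The randomization test permutes
group labels (preserving sizes) and compares $|d^\*|$ with the observed
$|d|$; when $\binom{n}{n_a} \le 20{,}000$ all splits are enumerated and
the p-value is exact (the identity split guarantees $p > 0$); otherwise
the seeded Monte-Carlo estimate uses the add-one form
$p = (1 + \#\{|d^\*| \ge |d|\})/(1 + B)$, which can never be zero. The
permutation unit is the track; the test answers "are these two pools of
tracks exchangeable?".

The replicate-aware alternative treats the biological repeat as the
experimental unit: per bootstrap iteration, tracks are resampled with
replacement *within* each repeat, repeat means are averaged into a group
mean, and the two bootstrap distributions of group means are compared with
a Welch $t$-test. Both tests are reported because they answer different
questions; neither replaces the other. Multiple-testing adjustment is
Bonferroni over the number of condition pairs (the only adjustment
offered, deliberately).

Boxplot exports follow the Tukey convention (whiskers at the most extreme
datum within 1.5×IQR of the box). "Axis limits of 10× the interquartile
range" is implemented as median ± 5×IQR per metric — a span of ten IQRs
centred on the pooled median — and recorded as plot metadata rather than
applied destructively to the data.

## Quality control

Replicate/FOV similarity trees summarise each group by the *median* of
each selected metric (robust to outlier tracks), z-score the summaries
across groups so that large-magnitude metrics (areas, total distances)
cannot dominate, and agglomerate with complete linkage on
$1 - \text{cosine similarity}$. Balanced resampling downsamples every
condition × repeat cell to the smallest cell without replacement, seeded;
the accompanying check runs a two-sample Kolmogorov–Smirnov test per
condition and metric between original and resampled values — a
distribution-shape-sensitive test chosen so that biased (non-random)
subsampling is caught, not just mean shifts.

## Embedding and density clustering

Feature matrices are z-scored per metric; tracks with any non-finite
selected metric are dropped with a reported count (tortuosity is NaN for
closed loops, so this is routine, not exceptional), and constant columns
are dropped with a warning. UMAP (via uwot, single-threaded) and t-SNE
(via Rtsne) run with fixed seeds; defaults are `n_neighbors = 10`,
`min_dist = 0`, two output dimensions — settings commonly used for
track-metric embeddings. For t-SNE, `n_neighbors` maps to the perplexity,
capped at $(n-1)/3$.

HDBSCAN is implemented in the package itself (R/hdbscan.R): core
distances from the `min_samples`-nearest neighbour, mutual-reachability
distances, single-linkage agglomeration, a condensed tree under
`min_cluster_size`, and excess-of-mass cluster selection, with `-1` as the
noise label. It was written here because no HDBSCAN implementation exists
in the package's dependency stack; it reproduces the reference behaviour
(including on mixed blob + noise scenes) and is validated against planted
ground truth in the test suite. Two deliberate conventions:

* `allow_single_cluster` defaults to `FALSE`, matching the reference
  implementations: a dataset whose density hierarchy never splits (for
  example uniform noise, or one single tight mass) is all noise. Set it
  to `TRUE` when a lone cluster is a meaningful outcome.
* Cluster labels are renumbered deterministically by first member index,
  and every seed used is logged in run manifests.

Both Euclidean and Canberra metrics are supported; the choice is
user-facing configuration, not automatic — collective-migration data with
very similar tracks may only separate under Canberra.

Fingerprints report, per condition, the percentage of its tracks in each
cluster *including* a noise category, so each row sums to exactly 100 and
no track disappears from the accounting. Cluster profiles z-score each
metric across cluster means (not across tracks): they display variation
among clusters, and a metric with equal cluster means yields a zero row
(0/0 guarded). Exemplars are the $k$ tracks nearest their cluster
centroid in the z-scored feature space, ties broken by track id.

## Spatial analysis

Ripley's K uses the plain estimator
$\hat K(r) = |A| / (n(n-1)) \sum_{i \ne j} 1[d_{ij} \le r]$ with
$L(r) = \sqrt{\hat K(r)/\pi}$, reported as $L(r) - r$. No analytic edge
correction is applied; instead, significance is judged against pointwise
quantile envelopes from seeded uniform simulations *in the same window*,
so observation and null share the same edge bias. Each track contributes
one point — its first-frame position by default (configurable to the mean
position or a fixed frame) — to avoid temporal pseudo-replication from
counting every frame of every track.

Region-of-interest distances are unsigned Euclidean distances to the
boundary: for polygons/polylines, the minimum point-to-segment distance;
for binary masks, the distance to the nearest boundary-pixel centre times
the pixel size, where boundary pixels are mask pixels 4-adjacent to
non-mask pixels *inside* the image (the image frame is not a biological
edge). The two representations of the same straight edge agree to within
one pixel. The edge is static per field of view; per-frame moving edges
are out of scope. Track-level proximity metrics summarise the distance
series, with `DirectionMovement_edge = EndDistance − StartDistance`
(positive = moving away over time) and `TrendSlope_edge` the
least-squares slope of distance against time. The close/far split labels
`MaxDistance_edge < threshold` (default 75 length units) as close, with
exact-threshold values assigned to close as the documented boundary rule.

## The synthetic generator

The generator emulates the structural features the pipeline cares about —
a condition/repeat/FOV hierarchy, per-condition motility regimes, frame
gaps, and a leading-edge proximity scene — not microscopy images. Tracks
are persistent-biased random walks: the step direction is the normalized
mix `persistence * previous + (1 - persistence) * random_unit`, step
lengths are normal truncated at zero with mean `speed_mean * dt` (the
truncation bias is negligible at the default `speed_sd ≤ speed_mean / 3`;
at much larger spreads the realised mean exceeds the nominal one), a
constant `bias_vector` adds drift, frames drop i.i.d. to create gaps, and
tracks reflect at the field borders (preserving track counts; clipped
tracks are flagged in the ground truth). Defaults (30 frames, speed
1 ± 0.25 per frame interval, persistence 0.5, 500-unit fields) are in the
range of typical cell-migration time-lapse experiments at ~minute
sampling.

What the generator does *not* emulate — segmentation errors, track
switching, division, density-dependent interactions, heterogeneous
per-cell speeds within a condition — bounds what green tests mean: they
certify the computations and their calibration, not robustness to
upstream tracking artefacts.

The leading-edge scene places a vertical edge and lets a stated fraction
of tracks approach it at constant speed without ever crossing it, so
their distance series is exactly linear and the recovered trend slope
must equal `-approach_speed` to numerical precision; the remaining tracks
wander with zero expected drift.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale: 1,000
tracks for the metric-oracle comparison, 500 null replicates at 1,000
permutations each for test calibration, 500 tracks per group for
effect-size recovery, 600 points for clustering recovery, 200 simulations
for the Ripley null, 100-simulation envelopes over 20 seeds for the
clustered alternative. These sizes give sampling error comfortably inside
the tolerances being checked while keeping a full run in tens of seconds.
Every stochastic step takes an explicit seed; identical inputs and seeds
give byte-identical CSV artifacts (numbers are written with readr's
shortest round-trip representation), and the CLI records all seeds in its
run manifests.

## Known limitations

* Lineage (splits/merges) is pass-through only: imported TrackMate columns
  such as `NUMBER_SPLITS` are carried, never computed.
* Spatial analysis is 2-D + time; 3-D datasets are accepted everywhere
  else.
* No mean-squared-displacement/diffusion fitting, no gap interpolation,
  no spline smoothing, and no FDR procedures beyond Bonferroni.
* The Ripley estimator is uncorrected by design; its absolute values at
  radii approaching the window size are biased and only the envelope
  comparison is meaningful there.
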