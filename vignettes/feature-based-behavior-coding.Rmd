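---
title: "Feature-based behavior coding: method, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based behavior coding: method, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbbc)
```

## The problem and the model

Pose-estimation backends reduce video to keypoint detections: per frame,
per person, per anatomical landmark, an image coordinate `(x, y)` in
pixels and a detection confidence. Behavior coding asks for something
categorical instead — which of a small set of behaviors is occurring in
each frame. FBBC bridges the two with an explicitly interpretable chain:

```
track --> features --> mix/norm --> thin --> 2-D embedding --> clusters --> timeline
```

Unlike end-to-end classifiers, every intermediate object is a table a
researcher can inspect, plot and archive. The package implements the chain
as pure functions over tibbles; nothing requires a display or the original
video.

### Coordinates

Image convention throughout: origin at the top-left, x rightward,
y **downward**, units pixels, frames indexed from 0, timestamps
`frame / fps * 1000` ms. The y-down frame is why the scalar cross product
follows a left-handed sign convention: for `u = a − o` and `v = b − o`,
`u_x v_y − u_y v_x` is positive when `v` lies clockwise of `u` *as seen on
screen*. The sign flip relative to the mathematical (y-up) convention is
deliberate and documented rather than corrected, because practitioners
read these features against the video frame.

### Features

Six elementary operations cover the feature set: `position_x`/`position_y`
(px), `speed` (px/s), `distance` (px), `dot_product` and `cross_product`
(px²). Speed uses a backward difference — displacement from the previous
retained frame over the elapsed time — with the first frame missing; this
is the simplest contract consistent with "displacement per unit time", and
it is documented so users can offset if they need centered estimates.
Cross and dot products are reported raw, not normalized by vector lengths:
scaling belongs to the mix/norm stage, and keeping the stages orthogonal
means a cross product file can be re-normalized later without recomputing
geometry. Degenerate triples (coincident keypoints) yield 0 rather than an
error, since transient keypoint overlap is common in real tracks.

Missingness is a first-class value: a feature touching a missing
coordinate is missing, with no silent imputation anywhere in the chain.
Low-confidence detections are *not* dropped at ingest — `filter_confidence()`
applies that policy explicitly so ingest stays lossless.

The built-in `desk_task` recipe pairs the neck x-coordinate (upper-body
side-to-side movement) with four cross products over the right-arm
keypoints 5, 6, 8, 10 (with `V[i,j]` the vector from keypoint i to j):
`shoulder_left = V[5,10] × V[5,6]`, `hand = V[10,8] × V[10,5]`,
`shoulder_right = V[6,5] × V[6,8]`, `elbow = V[8,6] × V[8,10]`. Each
product changes sign when the third point crosses the line through the
other two, so together they characterize arm posture compactly.

### Mix/norm

Min–max normalization maps each column onto [0, 1] independently, so
pixel-scale positions and px²-scale cross products contribute comparably
to embedding distances. Two conventions the original data sources leave
open are fixed here: a constant column maps to all zeros (with a warning)
rather than NaN, so it cannot poison the embedding; and binarization uses
`x ≥ threshold → 1`. Concatenation aligns series on the intersection of
their frames — scene filtering and thinning legitimately desynchronize
series, so an inner join with a logged drop count is friendlier than an
error. Division by zero in column arithmetic yields missing, again logged.

### Scenes

Scenes are half-open `[start_ms, end_ms)` intervals. Half-open intervals
compose: adjacent scenes never double-count a boundary frame, filtering is
idempotent, and the retained set is exactly the union over scenes. Scene
filtering is type-generic (tracks or feature series) since nothing in the
method fixes whether scenes are applied before or after featurization.

### Thinning and embedding

Thinning retains every k-th row. Its purpose is statistical, not just
computational: transitional frames — postures between two behaviors — blur
the boundaries between clusters, and thinning removes most of them. At
29.97 fps a step of 5 spaces rows ~0.17 s apart, which suits manipulation
tasks; faster behavior needs a smaller step, and the right amount is
worth exploring per data set.

The 2-D embedding uses UMAP (via `uwot`, spectral initialization,
single-threaded so runs are exactly reproducible from the recorded seed).
`n_neighbors` (default 20) and `min_dist` (default 0.1) matter most:
20 or 50 neighbors with `min_dist` 0.1 usually give well-separated
scatter plots, but neither is switched silently — the parameters are
explicit in `embed_params()` and recorded, with the seed and the embedded
columns, in a provenance sidecar next to every saved embedding. The
embedding is always two-dimensional: the coded output is meant to be read
off a scatter plot, and 2-D keeps picker-based clustering meaningful.
Rows with any missing selected feature are dropped before embedding (with
a count) because neighbor distances need complete vectors; the dropped
frames are excluded from the embedding's source frames, and the timeline
stage treats them like any other thinned gap.

### Clustering and the timeline

Interactive scatter-plot clustering is replayed headlessly by
`assign_by_pick()`: every point within `picker_range` of the picked
location joins the cluster, later picks overwriting earlier ones —
the semantics of interactive reassignment. One deliberate difference from
a GUI: the radius is measured in embedding coordinate units, not screen
pixels, because a headless tool has no screen geometry.

`auto_cluster()` is the programmatic stand-in needed for unattended runs.
With `k` given it is k-means (nstart 10, seeded). With `k = NULL` it uses
a connectivity heuristic: single-linkage merge heights are scanned for the
largest relative gap (ratio ≥ 2, up to 15 clusters), the dendrogram is cut
there, and groups smaller than `max(5, 1%)` of points are left unassigned
as sparse noise. On the well-separated blobs that thinning plus
normalization aim to produce, the between-blob single-linkage heights
exceed the within-blob heights by an order of magnitude, so the gap
criterion needs no tuning; on genuinely unclustered data the ratio test
fails and everything becomes one cluster, which is the honest answer.

`build_timeline()` converts thinned cluster labels back into a per-frame
code sequence by hold-forward: each coded point labels frames from its own
source frame up to (not including) the next retained source frame. Some
gap rule is unavoidable once thinning has happened; hold-forward is the
simplest order-preserving one, and its error is bounded by the thinning
step around each true behavior switch — which is why agreement with ground
truth is evaluated excluding a ±step window around transitions. Frames
before the first retained frame, and frames whose point is unassigned,
code as `NONE`. The per-frame and run-length interval exports are
mutually convertible without loss.

## File formats

* **Track/feature container**: Feather v2 (Apache Arrow) — columnar,
  binary, bit-exact for doubles, preserves NA, and carries the metadata
  (fps, video name, frame size, keypoint scheme, provenance) inside the
  file. A plain-text CSV mirror is always writable. Layout convention:
  `<video_dir>/trk/<stem>.track`, features under
  `<video_dir>/calc/<subfolder>/`.
* **DeepLabCut `.h5`**: both pandas layouts are read — the "fixed" layout
  (level/label string tables plus a values block) and the "table" layout,
  whose column tuples are recovered from the restricted protocol-0 pickle
  text pandas embeds in an attribute. The writer emits the fixed layout
  and is verified against `pandas.read_hdf` itself. The dialect stores no
  frame rate, so `fps` is required at import and kept in track metadata
  thereafter. Bodyparts are named, not numbered: ids default to order of
  appearance unless a name→id map is supplied, and the mapping used is
  recorded on the returned track.

## The simulator: what it emulates and what it does not

`desk_task_spec()` defines the package's reference study conditions: five
posture regimes over the Halpe26 upper-body subset (ids 5, 6, 8, 9, 10,
18) in a nominal 640×480 frame at 29.97 fps — reaching left, hand raised
on resting elbow, hand near the face, reaching right, and using the left
hand with the right arm at rest. Regimes evolve as a first-order Markov
chain sampled per frame (stay probability 0.985, mean dwell ≈ 2.2 s over
a 120 s recording) and keypoints are the regime template plus independent
Gaussian jitter of 3 px — the magnitude of frame-to-frame jitter a modern
pose backend produces on a seated subject. The template geometry was
checked at design time: after min–max normalization the five regime
centroids are pairwise ≥ 0.5 apart in the 5-D feature space while the
jitter-induced spread per dimension is an order of magnitude smaller, so
the separability premise of the method holds by construction.

What the simulator deliberately does **not** model: biomechanics (limbs
teleport between templates at a regime switch), dwell-time distributions
beyond geometric, occlusion and detection dropouts, confidence
degradation, camera distortion, or multiple interacting people. Passing
the synthetic end-to-end checks therefore demonstrates that the chain is
*correct* — features computed right, embedding reproducible, labels
propagated exactly — not that clustering will be this clean on real
video, where posture classes overlap and transitions are gradual.

## Numerical choices and degenerate inputs

* Geometry is evaluated in double precision directly from the defining
  formulas; the cross product agrees with an independent shoelace-
  determinant oracle to ~1e-14 relative.
* KDE dwell maps use a Gaussian product kernel evaluated at bin centers,
  normalized so the bin-weighted discrete sum approximates 1; the default
  bandwidth is a per-axis Silverman-style rule (`bw.nrd0`), falling back
  to 1 px for constant data.
* Speed on a single-frame track, embedding with fewer than
  `n_neighbors + 1` complete rows, empty scene tables, empty assignments
  and all-missing KDE inputs raise typed degenerate-input errors rather
  than returning empty objects.
* All randomness (simulation, embedding, k-means) flows through explicit
  seeds, executed under a local RNG scope so library calls never disturb
  the caller's random stream. Identical configs and seeds reproduce every
  pipeline artifact byte-for-byte.

## Problem sizes used in the checks

The end-to-end checks simulate the default 120 s desk task (3596 frames,
720 embedded points after thinning by 5) and repeat the full pipeline over
ten seeds, reporting medians; geometry oracles use 1000 random triples.
These sizes give stable medians while keeping a full verification run in
the tens of seconds on one core.

## Known limitations

* Person identity is taken as given; ID swaps from the upstream tracker
  are not repaired.
* Only 2-D embeddings are produced, and UMAP is the only backend.
* `auto_cluster`'s gap heuristic targets well-separated clusters; heavily
  overlapping behavior classes call for the pick-script workflow (or an
  explicit `k`) instead.
* The agreement metric matches codes to regimes greedily by overlap;
  with badly fragmented clusterings a one-to-one optimal matching could
  differ slightly.
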