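---
title: "Segmenting starch granules: watershed, critical points, and fuzzy merging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting starch granules: watershed, critical points, and fuzzy merging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starchseg)
```

## The problem

Starch granules imaged under bright-field microscopy appear as dark, round
or nearly round particles on a light background. Counting them and measuring
their position, shape and size is the basis of quantitative starch
morphometry, but granules cluster and overlap, so a plain
connected-component analysis merges touching granules and a watershed on a
distance map splits single granules into several fragments
(*oversegmentation*). `starchseg` implements a complete pipeline that
accepts the watershed's oversegmentation and then repairs it:

1. **Threshold** the image with the iterative class-mean-midpoint (ISODATA)
   scheme: starting from the image mean, split pixels at the current
   threshold $T$ into dark and light classes with means $\mu_1, \mu_2$ and
   update $T \leftarrow (\mu_1 + \mu_2)/2$ until the change drops below
   $\varepsilon$ (default 0.2 intensity units). Pixels strictly below $T$
   are granule foreground; pixels at $T$ are background (the update rule
   leaves equality unassigned, and a total partition is required).
2. **Chamfer distance transform** of the binary mask with the classical
   integer weight pair (3, 4), divided by 3, computed by the two-pass
   forward/backward raster scan. Pixels outside the image count as
   background so granules touching the border stay bounded.
3. **Meyer watershed**: each regional-maximum plateau of the distance map
   seeds a catchment basin; basins are flooded outward from high to low
   distance through a priority queue restricted to the foreground, with
   deterministic first-come tie-breaking. No maxima suppression is applied:
   the method deliberately accepts oversegmentation and corrects it
   downstream, so smoothing the distance map here would change the method.
4. **Roundness screen**: each segment's roundness $R = 4\pi S / L^2$ (area
   $S$, perimeter $L$) is compared against a threshold (default 0.70; the
   useful range is 0.70–0.75). Fragments of a round granule are elongated
   slivers with small $R$ and are flagged as oversegments outright.
5. **GVF critical points**: a fragment that covers about half a granule can
   be rounder than the threshold (an ideal half-disk has
   $R = 2\pi^2/(\pi+2)^2 \approx 0.746$), so a second, topological criterion
   is applied to the remaining segments: a genuine granule contains an
   interior point where the gradient vector flow field vanishes and points
   outward all around — a source of the field. Segments without such a
   point are oversegments.
6. **Fuzzy c-means merging**: within each connected foreground blob,
   oversegments are merged into the segments that passed both tests
   ("core" segments), using fuzzy c-means over weighted features with one
   cluster per core segment.

The granule count is the number of core segments; the final label map and
per-granule report (area, perimeter, roundness, centroid, equivalent
diameter, intensity statistics) are written by `write_pipeline_outputs()`.

## The gradient vector flow field

The GVF is the vector field $v(x, y) = (u, v)$ minimizing

$$E = \iint \mu\,(|\nabla u|^2 + |\nabla v|^2)
      + |\nabla f|^2\,|v - \nabla f|^2 \; dx\,dy,$$

where $f$ is an edge map — here the gradient magnitude of the
Gaussian-smoothed image (σ = 1.5 px), normalized to $[0,1]$. Near edges the
data term pins $v$ to $\nabla f$; elsewhere the regularization diffuses the
edge gradients smoothly into homogeneous regions. Inside a dark granule the
result points outward toward the boundary, vanishing at an interior source.

We solve the Euler equations by explicit time stepping,
$u_{t+1} = u_t + \Delta t\,[\mu \nabla^2 u_t - b\,(u_t - f_x)]$ with
$b = f_x^2 + f_y^2$ (and the $v$ analogue). Three numerical choices matter:

* **Time step.** The diffusion-only CFL bound $\Delta t \le 1/(4\mu)$ is
  *not* sufficient: the reaction term adds $b$ to the pointwise stiffness
  and an overstepped iteration diverges explosively. We use
  $\Delta t = 1/(4\mu + \max b)$.
* **Convergence.** The defaults are `max_iter = 5000`, `tol = 1e-5` (on the
  largest per-pixel update). These are deliberately strict: the boundary
  signal has to diffuse to granule centres, 15–30 px from the nearest edge,
  and a looser tolerance halts while the interior still carries only the
  initialization. On 320×320 scenes the solver typically converges in
  2000–4000 iterations (a few seconds in compiled code).
* **Critical-point test.** A candidate pixel must be a local minimum of the
  field magnitude, and the field probed 3 px away in each of the 8 compass
  directions must align with that direction (cosine similarity > 0.90) in
  at least 7 of 8 directions. The "7 of 8" and "0.90" values are the
  method's decision rule; the 3 px probe offset is a numerical choice.
  The field zero generically falls between pixels — at a 1 px offset a
  half-pixel misalignment alone tilts the probed direction by ~26°
  (cosine 0.894), failing the 0.90 cut for perfectly good granules — and
  immediately around the zero the field is weak enough for image noise to
  bend it. Probing 3 px out samples field clearly above the noise while
  staying well inside the smallest granules targeted (radius ~15 px), so
  the test responds to the field topology rather than to sub-pixel
  placement. The search is
  confined to the segment's pixels within
  $\max(3, 0.75\,r_{\mathrm{eq}})$ of its centroid, with
  $r_{\mathrm{eq}} = \sqrt{S/\pi}$. The window is generous because the
  field source of a partially overlapped granule is displaced toward the
  overlap; since candidates are restricted to the segment's own pixels, a
  wider window cannot credit a fragment with a zero that belongs to a
  neighbouring segment.

The zero-gradient requirement is implemented as
local-minimum-of-magnitude rather than an absolute epsilon: the discrete
field never vanishes exactly. The cosine similarity is clamped to
$[0, 1]$ — anti-parallel directions score 0.

## Fuzzy c-means merging

Merging is confined to a *merge group*: one 8-connected foreground blob and
the watershed segments inside it (only adjacent segments can be fragments
of one granule). Each member segment contributes a feature vector of mean
intensity, intensity variance, and the distance from its centroid to the
blob centroid, weighted 0.25 / 0.25 / 1.0 — the distance dominates because
only nearby segments should merge. The weights are applied as coordinate
scaling, so the standard fuzzy c-means updates with Euclidean distance
realize the weighted metric.

FCM minimizes $J = \sum_{i,k} u_{ik}^m \, d^2(x_k, v_i)$ subject to
$\sum_i u_{ik} = 1$, alternating the membership and centre updates with
fuzzifier $m = 2$, tolerance $10^{-4}$ on centre movement, at most 100
iterations (the usual textbook settings; the method fixes none of them).
The number of clusters is the number of core segments in the group, and
centres are initialized at the core feature vectors, which ties cluster
$i$ to core $i$ throughout. Each oversegment then joins the core with its
highest membership, with an adjacency repair: if that core's territory
(core plus already-merged fragments) does not touch the oversegment, the
adjacent core with the next-highest membership is taken instead, and
assignment passes repeat while territories grow. A datum coinciding with a
centre receives full membership there. Groups holding oversegments but no
core cannot be merged and are left unchanged with a warning.

Two ambiguities were resolved as follows. The distance feature is the
segment-to-blob-centre distance (not pairwise segment distances), matching
the role of the ROI centre in the feature description. The feature weights
are applied to raw, incommensurate units (intensity, intensity², pixels) as
stated; no normalization is interposed, and the merge outcome is dominated
by the distance feature as intended.

## Measurement conventions

The perimeter is measured by Freeman chain-code tracing of the outer
boundary (Moore neighbourhood) with Kulpa's bias-corrected step weights —
0.948 for orthogonal and 1.343 for diagonal steps; interior holes are
ignored, and an isolated pixel counts the unit-square perimeter 4. The
correction matters: plain weights of 1 and $\sqrt 2$ overestimate a digital
circle's perimeter by ~5%, dragging an ideal disk's roundness down to
≈ 0.90, while naive pixel-edge counting would push it to ≈ 0.79; either
way the 0.70–0.75 threshold would lose its meaning. With the corrected
weights, digital disks of radius 15–30 measure roundness 0.99–1.03, and
the 0.70 default separates disk-like segments from slivers as intended. Segments smaller than
`min_area` (9 px) are flagged as oversegments directly — a sub-resolution
sliver cannot host a critical point. Intensity variance is the population
variance over the segment's pixels of the original image.

## The synthetic scene generator

The microscopy images behind the method are not distributed, so validation
uses seeded synthetic scenes (`scene_spec()` / `generate_scene()`): dark
granules (default intensity 60) on a light background (180), radii 15–30
px, Gaussian edge blur (σ = 1 px), additive Gaussian noise (σ = 5, small
against the 120-unit contrast), and a maximum centre-distance deficit of
30% of the radius sum (`overlap_fraction = 0.3`). These defaults give the
bimodal histogram that stained bright-field starch images show. Ground
truth assigns overlap pixels to the nearer granule centre, mirroring the
distance-based cut a watershed would make, so intersection-over-union
scores (`score_against_truth()`) are meaningful.

Overlaps are rendered as stacked absorbers: each granule covering a pixel
multiplies the transmitted intensity by `fg/bg`, so a two-granule overlap
is darker than either granule alone (Beer–Lambert). This matches
transmitted-light images of stained granules and is essential to the
critical-point criterion: a uniformly dark two-granule blob has no internal
intensity structure, hence a single field source at the blob centroid, and
no method working from intensity alone could attribute one source to each
granule. What the generator does *not* emulate: internal granule texture
(hilum, growth rings), uneven illumination, out-of-focus blur, and
non-elliptical granule outlines. Passing tests on these scenes therefore
demonstrate the pipeline's geometric and topological behaviour — splitting,
classification, merging — not robustness to every artefact of real
micrographs.

The validation suite runs the full pipeline on 50 seeded 320×320 scenes
with 3–10 granules each and requires the recovered granule count to equal
the truth in at least 90% of scenes; single-granule scenes (disks and
ellipses up to axis ratio 1.5) must yield exactly one critical point within
2 px of the true centre. The residual failures are heavily overlapped
pairs in which one granule's field source is swallowed by its neighbour —
the same configuration the method documents as its blind spot (a fragment
covering more than half a granule passes both tests).

## Degenerate inputs and edge cases

* Constant images: the threshold is degenerate; the pipeline warns and
  returns zero granules.
* A class emptying during threshold iteration: its mean is taken as the
  current threshold, keeping the update defined.
* Pixels exactly at the threshold: background.
* Empty foreground after thresholding: empty report, warning, success.
* Watershed ties: first-come in deterministic raster order; reruns are
  byte-identical.
* A zero-core merge group: left unmerged with a warning; its segments stay
  in the label map but count no granules.

## Limitations

The roundness threshold presumes round granules; species with elongated or
compound granules would need a different shape screen. The critical-point
criterion cannot split a fragment that covers more than half a granule, and
requires enough intensity contrast at granule boundaries for the GVF to
carry signal into granule interiors. Merging assumes oversegments and their
parent cores share a connected foreground blob; granules split across blobs
by the thresholding stage will not be reunited.
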