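# starchseg

Segmentation and morphometry of starch granules in bright-field microscopy
images, for plant scientists and breeders who count and measure granules to
characterize starch phenotypes. Stained granules appear as dark, round
particles on a light background; they cluster and overlap, so naive
segmentation either fuses touching granules or shatters single granules
into fragments. `starchseg` implements a pipeline that deliberately
oversegments and then repairs itself:

1. **Iterative thresholding** (ISODATA): repeat
   *T* ← (*μ*₁ + *μ*₂)/2, where *μ*₁ and *μ*₂ are the mean intensities of
   the pixels below and above *T*, until the change is below ε (0.2);
   pixels below *T* are granule foreground.
2. **Chamfer distance transform** of the mask (two-pass, integer weights
   3/4, values divided by 3), then **Meyer watershed**: every
   regional-maximum plateau of the distance map seeds one segment.
3. **Oversegment identification.** A segment is a fragment (an
   "oversegment") if its roundness *R* = 4π*S*/*L*² falls below 0.70, or —
   for rounder segments — if it contains no *critical point* of the
   gradient vector flow (GVF) field: an interior field zero whose
   surroundings point outward in ≥ 7 of 8 compass directions with cosine
   similarity > 0.90. One such source exists per genuine granule.
4. **Fuzzy c-means merging.** Within each connected foreground blob,
   fragments are merged into the segments that passed both tests, using
   FCM over features (mean intensity, intensity variance, distance to the
   blob centre) weighted 0.25/0.25/1.0, one cluster per accepted granule,
   cluster centres initialized at the granule features.

The granule count is the number of segments passing both criteria; outputs
are a label map (16-bit TIFF), an RGB overlay, and a CSV morphometry report
(area, perimeter, roundness, centroid, equivalent diameter, intensity
statistics).

## Worked example

The package generates its own ground-truthed scenes, so the full pipeline
can be demonstrated without any image files:

```r
library(starchseg)

scene <- generate_scene(scene_spec(n_granules = 6, seed = 42))
result <- run_pipeline(scene$image, verbose = TRUE)
#> threshold converged: T0 = 164.6 -> T = 120.48 (3 iterations)
#> watershed: 9 segments
#> classification: 6 core, 3 oversegment
#> merge: 3 oversegments merged, 6 granules

result
#> granule segmentation pipeline
#>   threshold: T0 = 164.6 -> T = 120.48
#>   watershed segments: 9
#>   core segments (granules): 6
#>   oversegments merged: 3

score_against_truth(result$merged_labels, scene$truth_labels)[
  c("n_truth", "n_pred", "n_resolved")]
#> $n_truth
#> [1] 6
#> $n_pred
#> [1] 6
#> $n_resolved
#> [1] 6
```

The threshold settles between the two histogram modes (granules ~60,
background ~180); the watershed splits the six granules into nine
segments; three fragments fail the roundness or critical-point test and
are merged back, recovering all six granules with correct extents
(IoU ≥ 0.5 against ground truth). `write_pipeline_outputs()` writes the
label map, overlay, report and a JSON summary; `inst/cli/starchseg.R`
wraps the same calls as `run` / `synth` / `merge-only` shell subcommands.

A classic worked example ships with the package: the segment table of a
sweet-potato starch micrograph whose watershed produced 15 segments
(background + 7 granules + 7 fragments):

```r
tab <- classify_segment_table(reference_segment_table())
tab$label[tab$classification == "core"]
#> [1]  2  7  8  9 10 14 15
```

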