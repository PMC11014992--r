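# mitomorph

Quantification of confocal images of skeletal muscle: mitochondrial
instance segmentation and morphometry, membrane-potential area ratios,
lipid-droplet densities, and ROI-based fluorescence measures — with
built-in synthetic image generators that provide exact ground truth, so
the whole pipeline is testable without any microscope data.

## Who this is for

Muscle and mitochondria labs quantifying confocal stacks the macro way
(FIJI-style chains: project → 8-bit → blur → despeckle → auto-threshold →
measure) who want those chains as tested, scriptable, seed-reproducible R
functions, plus a principled segmentation route for per-mitochondrion
morphometry.

## The core method

Mitochondria are segmented per image in three steps:

1. **Background removal** — 2-class k-means on pixel intensity (Lloyd,
   deterministic percentile initialisation); the lower-mean cluster is
   background.
2. **Density-based clustering** — every retained pixel becomes a feature
   row (x, y, intensity rescaled to [0, w], w = 10 by default) and DBSCAN
   groups them with the two parameters *minClusterSize* (minPts) and
   *searchRadius* (eps). Noise pixels return to background; each cluster
   is one mitochondrion.
3. **Monte-Carlo tuning** — the two parameters are sampled (minPts uniform
   on [3, 50], eps log-uniform on [0.5, 5], 200 iterations by default)
   and scored against a manually annotated reference image by
   intersection-over-union,

   IOU(A, B) = |A ∩ B| / |A ∪ B|,

   keeping the argmax and stopping early once IOU > 0.95. The tuned pair
   is then applied to every image of the experiment.

Instance areas are pixel counts × (pixel size)² in µm², binned on
log10(area) at −0.5 and 0 into small / medium / large, summarised as
per-replicate percentages, and compared between groups with a Pearson
chi-square on the 2×3 table (df = 2).

The fluorescence measures follow their standard definitions: the active
mitochondria fraction is thresholded TMRE area over thresholded
MitoTracker area (both channels processed identically, IsoData
auto-threshold); lipid-droplet analysis is 8-connected particle counting
with a calibrated half-open size window and densities per mm²; TCCF is
integrated ROI intensity − ROI area × mean background; muscle attachment
is thresholded-foreground fraction inside a cuticle ROI.

## Worked example

```r
library(mitomorph)

# a calibrated synthetic image with exact ground truth
sim <- simulateMitoImage(mitoImageSpec(seed = 11L))
plane <- maxProject(sim$stack)
bg <- classifyBackground(plane)

# tune the two DBSCAN parameters against the annotation
tuned <- tuneParameters(plane, bg, binaryMask(sim$truth),
                        tuningConfig(seed = 12L))
tuned
#> TuningResult: best IOU 0.9994 (target > 0.95, met) after 1 iteration(s)
#>   best params: minClusterSize = 6, searchRadius = 3.287

lm <- segmentStack(sim$stack, bestParams(tuned))
lm
#> InstanceLabelMap: 512 x 512 px, 30 instance(s), 0.1 um/px

head(measureAreas(lm), 3)
#>   instance_id pixel_count area_um2  log10_area size_class
#> 1           1          93     0.93 -0.03151705     medium
#> 2           2          25     0.25 -0.60205999      small
#> 3           3          22     0.22 -0.65757732      small
```

The best sampled parameter pair segments the image at IOU 0.9994 against
ground truth and recovers all 30 planted instances; each row of the
morphometry table is one mitochondrion with its calibrated area and size
class. The membrane-potential measure recovers a designed active fraction
the same way:

```r
tc <- simulateTwoChannel(mitoImageSpec(seed = 5L), activeFraction = 0.6)
percentActiveMitochondria(tc$total, tc$active)$percent_active
#> [1] 60.89163
```

Batch runs go through `runAssay()` (or the `inst/cli/mitomorph` script),
which reads a YAML/flag configuration, writes CSV/JSON/TIFF results and a
provenance record, and is byte-deterministic for a fixed seed.

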