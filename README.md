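# fazseg

Automatic localization and precise segmentation of the **foveal avascular
zone (FAZ)** in en-face OCT angiography (OCT-A) images, with the area and
circularity biomarkers used to monitor diabetic retinopathy and retinal
vein occlusion.

The FAZ is the capillary-free region at the center of the fovea. Manual
delineation is slow and subject to inter-expert variability; `fazseg`
measures it deterministically from a single en-face raster (3 x 3 or
6 x 6 mm field, superficial or deep plexus).

## Method

`segment_faz()` runs the full pipeline:

1. min-max intensity normalization to [0, 1];
2. vascular enhancement with the grayscale **white top-hat** (image minus
   its opening with a flat disc), which keeps thin bright vessels and
   flattens the broad background;
3. vessel edge detection with a **Canny** detector whose hysteresis
   thresholds adapt to the mean image intensity
   (`low = 0.66·mean`, `high = 1.33·mean`), making the edge map invariant
   to global brightness;
4. candidate extraction: morphological **closing** of the edge network
   (seals inter-capillary gaps), **inversion** and **opening** (removes
   speckle); peripheral, eccentric and disperse components are discarded
   and the survivor with the **largest perimeter** becomes the
   preliminary FAZ;
5. precise segmentation by **erosion-seeded region growing with pixel
   addition and deletion**: each sweep recomputes the average region
   value (ARV) and accepts exactly the pixels with intensity in
   `[ARV − 0.3·ARV − f, ARV + 0.3·ARV + f]` (30 % relative tolerance
   plus a small absolute floor `f`), growing until a sweep changes
   nothing.

The result carries the two biomarkers

    area        A = a · mm² / (height · width)     [mm²]
    circularity C = 4πA / P²                        [0, 1]

with `a` the pixel count and `P` the perimeter (corner-corrected
chain-code estimator). Evaluation utilities implement the
centroid-in-reference localization criterion, the Jaccard index, Pearson
correlation of area series and circularity-tertile summaries. A seeded
phantom generator produces OCT-A-like images with exact ground truth so
the whole pipeline is testable without clinical data. See the methods
vignette (`vignettes/faz-segmentation-methods.Rmd`) for the full model
description and design rationale.

## Worked example

```r
library(fazseg)

# a synthetic 3 mm superficial capture with known ground truth
ph  <- generate_phantom(phantom_spec(field_mm = 3, faz_radius_mm = 0.32,
                                     irregularity = 0.25, seed = 11))
res <- segment_faz(ph$image)
res
#> <faz_segmentation> FAZ at (161.4, 160.2), area 0.3161 mm^2, circularity 0.914 (6 sweeps, converged)

jaccard_index(res$mask, ph$mask)       # 0.97  agreement with ground truth
compute_area_mm2(ph$mask, 3)           # 0.3257 mm^2 true area
```

The printed line reads: the FAZ centroid sits at pixel (161.4, 160.2)
(1-based row/col), its area is 0.3161 mm² — within 3 % of the 0.3257 mm²
ground truth — and its contour is fairly regular (circularity 0.914);
the region growing converged after 6 sweeps.

## Command line

A thin front-end is installed under `exec/`:

```sh
faz-seg segment  --field-mm 3 --out results/  scans/*.png
faz-seg evaluate --manifest data/manifest.csv --out eval/
faz-seg phantoms --out phantoms/ --n 20 --seed 1
```

`segment` writes a binary mask PNG and a JSON report (biomarkers,
centroids, full configuration) per image plus a batch CSV; `evaluate`
reads a manifest CSV (`image`, `mask`, `field_mm`, optional `subgroup`)
and writes per-image records, per-subgroup summaries (localization rate,
area correlation, mean Jaccard) and circularity-tertile tables;
`phantoms` writes a synthetic suite with its manifest. Pipeline
parameters come from a YAML file via `--config`; all keys and defaults
are documented in `?faz_config`.

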