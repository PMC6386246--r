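---
title: "Methods: automatic FAZ localization and segmentation in OCT-A images"
author: "fazseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic FAZ localization and segmentation in OCT-A images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fazseg)
```

## The problem

Angiography by optical coherence tomography (OCT-A) maps the perfused
retinal vasculature without injected contrast. At the center of the macula
lies the foveal avascular zone (FAZ), a capillary-free region whose area
and contour irregularity are established biomarkers for diabetic
retinopathy and retinal vein occlusion. Manual FAZ delineation is slow and
shows substantial intra- and inter-expert variability, so a deterministic
automatic measurement is clinically valuable.

`fazseg` segments the FAZ in single en-face OCT-A rasters (typically
320 x 320 px covering a 3 x 3 or 6 x 6 mm field, superficial or deep
plexus) and derives two biomarkers:

* **area** $A = a \cdot \mathrm{mm}^2 / (h \cdot w)$, where $a$ is the
  foreground pixel count, $\mathrm{mm}$ the physical field width and
  $h, w$ the raster dimensions;
* **circularity** $C = 4\pi A / P^2 \in [0, 1]$, with $P$ the region
  perimeter; 1 for a circle, decreasing with contour irregularity.

## The pipeline

`segment_faz()` chains five stages. The design premises are that the FAZ
is (i) roughly macula-centered, (ii) a low-intensity region with clear
contrast against its surround, and (iii) bounded by the perifoveal
capillaries.

1. **Normalization.** Intensities are min-max normalized to $[0, 1]$.
   A constant image is rejected as degenerate. Global min-max is the
   simplest contract that keeps all later thresholds scale-free.
2. **Vascular enhancement** (`white_tophat()`): the grayscale white
   top-hat, image minus its opening with a flat disc, preserves bright
   structures thinner than the disc (vessels) at full contrast and
   flattens the broad background. Default disc radius
   `round(width / 32)` (10 px at 320 px): comfortably above the largest
   vessel calibre (~4 px) and far below the FAZ diameter, so vessels pass
   and the macular background does not.
3. **Vessel edge detection** (`adaptive_canny()`): standard Canny stages
   (Gaussian blur, Sobel gradients, non-maximum suppression, hysteresis)
   with both hysteresis thresholds proportional to the mean intensity of
   the enhanced image: `low = 0.66 * mean`, `high = 1.33 * mean`,
   `sigma = 1` px. Because the gradient magnitude is linear in intensity,
   the edge map is *invariant to global intensity rescaling* — the
   operational meaning of thresholds that adapt to the image average, and
   the property the test suite checks directly. Only the thresholds
   adapt; `sigma` is fixed.
4. **Candidate extraction and selection.** A binary closing (disc,
   radius `round(width / 64)` = 5 px) seals inter-capillary gaps up to
   twice its radius, so avascular holes become isolated dark regions; a
   closing is used instead of a bare dilation because the erosion restores
   the vascular band to its true extent. After inversion, an opening
   (radius `round(width / 53)` = 6 px) deletes speckle. 8-connected
   components become candidates; three rules then discard what cannot be
   the FAZ:
   * *peripheral*: the component touches the border or its bounding box
     comes within 5 % of `min(h, w)` of it (capture-artifact bands and the
     inverted background live there);
   * *eccentric*: centroid farther than 80 % of `min(h, w)/2` from the
     image center;
   * *disperse*: solidity (pixel count / bounding-box area) below 0.3.
   The survivor with the **largest perimeter** is the preliminary FAZ;
   ties break by larger pixel count, then by centroid closest to the
   center. Perimeter rather than pixel count is used because a
   partially vessel-crossed FAZ can lose area but keeps its extent.
5. **Precise segmentation** (`erode_seed()` + `region_grow()`): the
   preliminary region is eroded (disc, radius 3 px) so the seed is surely
   inside the true FAZ, then grown on the *enhanced* image. Each sweep
   recomputes the average region value (ARV) and simultaneously adds
   every 8-neighbour whose intensity lies in
   $[\mathrm{ARV} - 0.3\,\mathrm{ARV} - f,\ \mathrm{ARV} + 0.3\,\mathrm{ARV} + f]$
   and deletes region pixels outside it; the loop stops when a sweep
   changes nothing.

## Parameters that matter

| key | default | unit | role |
|---|---|---|---|
| `tophat.selem_radius` | `round(width/32)` | px | vessel/background separation scale |
| `canny.sigma` | 1 | px | gradient smoothing |
| `canny.low_frac`, `canny.high_frac` | 0.66, 1.33 | x mean | adaptive hysteresis |
| `morph.close_radius` | `round(width/64)` | px | max sealable inter-capillary gap / 2 |
| `morph.open_radius` | `round(width/53)` | px | min surviving candidate half-width |
| `fp.border_margin_frac` | 0.05 | frac | peripheral rule |
| `fp.max_center_offset_frac` | 0.8 | frac | eccentric rule |
| `fp.min_solidity` | 0.3 | — | disperse rule |
| `grow.tolerance_frac` | 0.3 | — | relative acceptance band (30 %) |
| `grow.abs_floor` | 0.05 | intensity | absolute band widening |
| `grow.seed_erosion_radius` | 3 | px | seed safety margin |
| `grow.max_iterations` | 100 | sweeps | hard termination bound |

All keys are exposed through `faz_config()` and YAML files; every report
embeds the exact configuration used.

### Why the acceptance band has an absolute floor

The 30 % tolerance is relative to the ARV. On the top-hat image the FAZ
interior is a near-zero plateau (typical ARV ~ 0.06), so a purely
multiplicative band is ±0.02 — *narrower than the intensity noise* — and
the growth stalls at the eroded seed, leaving the "precise" segmentation
worse than the preliminary one. `grow.abs_floor` widens the band by an
absolute amount; its default 0.05 is roughly twice the typical
intensity-noise scale of the enhanced image and an order of magnitude
below the vessel contrast, so it restores growth across the dark plateau
without letting the region leak through vessel walls. Setting it to 0
recovers the strictly multiplicative rule.

### Region-growing semantics

Three further choices close gaps the add/delete description leaves open:

* **ARV update cadence** — recomputed once per sweep, and all of a
  sweep's additions/deletions use that one value, so the result does not
  depend on pixel order within a sweep.
* **Anchoring** — the eroded seed is never deleted; without this the
  deletion rule can evaporate the whole region on a noisy plateau.
* **Connectivity maintenance** — deletion can split the region; only the
  component containing the seed centroid is kept. With updates frozen and
  deletion disabled the procedure reduces exactly to interval-membership
  flood fill, which the tests verify against an independent BFS oracle.

## Numerical choices

* **Coordinates** are 1-based `(row, col)`, origin top-left — the native
  R matrix convention, used consistently in every module so no
  conversions occur at module boundaries.
* **Connectivity** is 8-connected everywhere (labelling, hysteresis,
  growing), so thin diagonal structures are never split.
* **Perimeter estimator**: Moore boundary tracing of each component's
  outer contour, converted to length with corner-corrected chain-code
  weights (0.980 per axial step, 1.406 per diagonal step, −0.091 per
  direction change). On a digital disc of radius 50 this is within ~1 %
  of $2\pi r$, while double-sided thin shapes are measured correctly
  (a 1 x 50 bar gets perimeter ≈ 96, hence circularity < 0.1). The same
  estimator drives candidate selection and the circularity biomarker, so
  the two are consistent. Isolated pixels count $\pi$; interior holes do
  not contribute.
* **Degenerate inputs**: constant images and images whose enhanced mean
  is zero raise errors; an image where no candidate survives the
  false-positive rules yields a *localization failure* result, not an
  exception. Seed erosion falls back to radius halving and finally to a
  single centroid pixel rather than emptying the seed.
* **Structuring elements** are flat digital discs of odd size
  `2 * radius + 1` throughout (EBImage brushes); all morphology uses the
  border-intersection convention, which the brute-force test oracles
  replicate.

## The phantom generator

`generate_phantom()` builds OCT-A-like images with exact ground truth so
every stage is testable without clinical data:

* the FAZ contour is $r(\theta) = r_0 (1 + \iota \sum_{k=2}^{6} a_k
  \cos(k\theta + \phi_k))$ — a low-order Fourier radius modulation whose
  amplitude $\iota$ dials circularity continuously from ~1 down into the
  strongly irregular diabetic range;
* vessels are meandering random-walk strokes whose count scales with the
  physical field width (a 6 mm capture images four times the retinal area
  of a 3 mm one) and whose calibres are sampled in physical units
  (9–38 µm) before conversion to pixels, so 6 mm phantoms show the
  thinner, denser mesh real captures do; the bright-pixel fraction lands
  near published perfusion densities (~0.4–0.5);
* an explicit perifoveal capillary ring runs along the FAZ boundary —
  capillaries terminate at the avascular border, as in real angiograms;
* deep style lowers vessel contrast (0.45 vs 0.85) and blurs more
  (sigma 1.1 vs 0.5 px), giving the diffuse, rough edges of deep-plexus
  projections;
* optional artifact bands darken one border, emulating capture errors;
* everything is driven by one integer seed and is bit-exactly
  reproducible.

What the phantoms do **not** emulate: physical speckle/decorrelation
statistics, projection artifacts of deep plexus imaging, pathology other
than contour irregularity (no capillary dropout away from the FAZ, no
micro-aneurysms), and motion artifacts beyond a uniform dark band.
Passing the synthetic suite therefore demonstrates the pipeline's
correctness under its stated premises, not clinical-grade performance on
real data.

## Validation set-up

The end-to-end suite uses 200 phantoms at 320 x 320 px cycling through
the four standard configurations (3/6 mm x superficial/deep), FAZ areas
uniform in 0.1–0.6 mm², irregularity uniform in 0–0.6, and a 10 % chance
of an artifact band; the oracle-equivalence suites use 50 random rasters
up to 32 x 32 (morphology) and 20 phantoms at 64 x 64 (region growing).
These sizes give stable statistics at interactive runtimes. Localization
is scored by the centroid-in-reference criterion on the *preliminary*
extraction; Jaccard, area correlation and circularity tertiles are
computed over the localized cases, mirroring how segmentation quality is
conventionally reported for this task.

## Known limitations

* The FAZ must be the largest well-formed avascular region near the
  image center; severe capillary dropout elsewhere can out-perimeter a
  very small FAZ (the characteristic failure mode on 6 mm images with
  small FAZs).
* The "peripheral / eccentric / disperse" thresholds are heuristics
  standing in for rules the task only describes qualitatively; they are
  exposed in the configuration for exactly that reason.
* Biomarkers are computed on the pixel grid; sub-pixel contour placement
  is out of scope.
* Only single en-face rasters are supported — no volumetric stacks, no
  DICOM ingestion.
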