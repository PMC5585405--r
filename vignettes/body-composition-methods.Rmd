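---
title: "Automated CT body composition: models, parameters and validation design"
author: "bodycompCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated CT body composition: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Single axial CT slices at three stations -- liver, abdomen (L4) and
mid-thigh -- carry most of the body-composition information that
epidemiological studies need, at a fraction of the radiation dose of a
volumetric scan.  Because CT reports calibrated Hounsfield units (HU),
tissue classes can be separated by fixed attenuation bands:

| band            | HU range        | used for                     |
|-----------------|-----------------|------------------------------|
| body vs air     | > -300          | body outline, table removal  |
| adipose tissue  | [-190, -30]     | all fat depots               |
| lean tissue     | (-30, +151]     | muscle, organs, liver        |
| cortical bone   | > +400          | bone removal (thigh)         |

Bands are treated as closed-below/open-above on the shared endpoint so
that adjacent bands partition the HU axis and no pixel is counted twice.
Thresholding alone cannot tell *visceral* from *subcutaneous* fat, nor
*subfascial* from *subcutaneous* thigh fat: those boundaries are defined
by enclosing lean structures (the abdominal muscle wall, the fascia
lata), not by attenuation.  Everything non-trivial in this package is
about recovering that enclosure information.

# The inside-lean-tissue (ILT) filter

For every pixel, `iltResponse()` shoots `nDir` equally spaced rays and
accumulates along each ray the *lean-tissue probability* of the samples,
where attenuation maps to probability through a linear ramp between `l1`
(probability 0) and `l2` (probability 1).  The per-pixel response pools
the `ceiling(dirPercent * nDir)` *smallest* directional accumulations,
and the map is divided by its global maximum so it spans [0, 1].

The pooling of the smallest directions is the essential idea.  A pixel
strictly inside a closed lean ring sees lean tissue in *every*
direction, so even its smallest accumulations are substantial.  A
subcutaneous pixel lies outside a convex lean boundary: the cone of
directions that ever hit the wall is strictly less than half the circle
(half-angle `asin(r_wall / r_pixel) <= 90` degrees), so with
`dirPercent = 0.5` the pooled sum is essentially zero -- subcutaneous
fat has much less lean tissue in about half of the probed directions.
This makes the subcutaneous/visceral separation a thresholding problem
with a very wide margin, and is why the filter tolerates thin or even
locally interrupted muscle walls (a 1-px gap perturbs the assignment of
well under 1% of adipose pixels: only a narrow angular window of rays
escapes through the gap, and only for pixels near it).

Parameter defaults, all exposed in `iltParams()` / the YAML config:

* `nDir = 32` directions, angles `2*pi*d/nDir` from the +column axis.
  Fewer directions quantize the escape cone; more cost linearly.
* `l1 = -30`, `l2 = +20` HU: the ramp straddles the adipose/lean
  boundary so partial-volume pixels contribute fractionally.
* `dirPercent = 0.5`, motivated above.
* `stepMm = min(spacing)`: one sample per pixel along the ray; bilinear
  interpolation (nearest-neighbour available) keeps the response nearly
  rotation invariant.
* `pmThreshold` per station, calibrated once on the default phantoms
  (below): 0.05 for the abdominal/liver cavity pass, 0.01 for the thigh
  SAT pass, 0.18 for the deep thigh pass.  The cavity value was chosen
  midway on a log scale between the largest response observed in
  subcutaneous fat across jittered phantoms (< 0.01) and the smallest
  interior response (~ 0.1 under thin-wall jitter); the thigh SAT pass
  separates exact zeros from the faint subfascial response (> 0.02)
  behind the thin fascia; the deep pass separates that faint rim from
  intermuscular islands (> 0.3).

Rays exclude their origin pixel and stop at the first sample outside
the grid.  Ties in the pooled sort are irrelevant (a sum over the k
smallest values is tie-invariant).  An all-air image maps to the all-zero
map rather than dividing by zero.  A plain-R reference implementation
(`iltResponseRef()`) with the same contract but an independent
ray-marching decomposition guards the optimized path in the tests to
1e-9.

# Liver attenuation

`segmentLiver()` needs only an *approximate* liver segmentation, because
the target quantity is mean tissue attenuation, not liver size.  The
pipeline is: lean-band threshold; Euclidean distance transform (DT1);
multiplication with the shape prior `P_liver`; quantile threshold of the
product to obtain a seed sample deep inside high-prior lean tissue; an
adaptive attenuation range `R = [p2.5, p97.5]` of the seed HU values
(clamped to the lean band; a mean +/- 2 SD rule is available); a
re-threshold of the original image by `R`; a second distance transform
(DT2) times the prior; a final quantile threshold; hole filling and
largest-component selection; and a least-squares Gaussian fit to the
1-HU histogram of the masked values, whose center is the reported
attenuation.

The subject-specific range `R` is what lets one atlas serve livers
anywhere in the 0--60 HU span that fatty infiltration produces: the
seed is located geometrically (distance times prior), then the
attenuation statistics adapt.  The Gaussian *center* is preferred over
the mean because it ignores a minority population in the mask (a 10%
contamination at -5 HU moves the mean by > 4 HU but the fitted center
by < 1.5 HU).  The final compactness step matters for stability: the
raw product threshold is ragged, and a 1-px erosion of a ragged mask
removes over half its pixels; after hole filling the same erosion
changes the estimate by < 0.2 HU.

The shape prior is built by `buildShapeAtlas()` from reference liver
masks, aligned by mapping each image's *cavity span* onto a canonical
unit rectangle (anisotropic scaling only -- subjects are supine, so no
rotation).  The cavity span is the bounding box of the non-lean interior
of the ILT inside mask: the inside mask itself includes the enclosing
muscle wall (tangential rays inside the wall accumulate lean tissue), so
the box is taken over the cavity contents instead.  Quantile thresholds
(`seedQuantile = 0.90`, `finalQuantile = 0.50` of the positive product
values) adapt to image size and prior sharpness where absolute
thresholds would not.  Whether the prior should be binarized before
multiplication is unknowable from the figure evidence; we multiply by
the continuous map, which weights distance by prior confidence.

# Abdominal VAT/SAT

`segmentVatSat()` is three steps: adipose threshold within the body;
ILT cavity mask (largest component, restricted to the body); and removal
of perispinal back fat via a `P_back` atlas aligned by the cavity
bounding box and thresholded at `backThreshold = 0.5`.  VAT is adipose
inside the cavity minus the back region, SAT is adipose outside the
cavity, and the three parts partition adipose-in-body *by construction*
-- the conservation checks in the tests verify the implementation, not
a numerical accident.  Inter/perimuscular fat other than the modelled
back region is assigned by the cavity mask alone; this reproduces the
known overestimation mechanism of the automated approach (fat within
the wall counts as VAT), which is accepted rather than patched.

The back prior deserves a caveat: thresholding a resampled probability
map at 0.5 erodes about one pixel from each edge of the region, so for
a thin perispinal ring the excluded region is a core sample rather than
full coverage.  On the phantom ensembles this costs a few tenths of a
percent of VAT Dice; lowering `backThreshold` trades that against
removing true VAT.

Manual sub-depot utilities: `splitSatByFascia()` classifies SAT pixels
as deep/superficial by comparing their polar radius about the body
center of gravity with the interpolated fascia radius at the same polar
angle, handling the anterior and posterior halves separately (the row
through the centroid is the split axis; a half is reported only when the
traced fascia spans it).  `splitVatByContour()` applies even-odd
point-in-polygon membership of pixel centers after rejecting
self-intersecting contours.

# Thigh composition

Per thigh (the two largest non-table components; one binary opening is
attempted if they touch): muscle and fat by bands, bone as the cortical
threshold with hole-filled marrow (marrow attenuation falls in the
adipose band but is not a depot), SAT as adipose outside the ILT inside
mask, and two alternatives for the subfascial/intermuscular split of the
remaining fat:

* **Method 1 (ILT):** a stricter second pass; fat inside the deep mask
  is IMAT, the rim under the fascia is SFAT.
* **Method 2 (morphological):** hole-fill the muscle + inner-fat region,
  shrink it by `depthMm` using the spacing-aware distance transform, fat
  in the shrunken zone is IMAT.

`depthMm` was calibrated with `calibrateThighParams()` on an 8-phantom
training ensemble, optimizing the truth-area correlation first and mean
Dice second: 7 mm was selected (the subfascial band sits 2--7 mm deep to
the fascia's outer surface once geometry jitter is included; a 5 mm cut
bisects it).  Both methods conserve fat exactly
(`SAT + SFAT + IMAT = adipose`) and agree on IMAT to Dice 1.0 on clean
concentric phantoms; on real images the published experience is that the
morphological method correlates slightly better, with SFAT much harder
than IMAT because the fascia is rarely visible.

Muscle attenuation is the plain mean over the muscle mask (Gaussian-fit
variant available for symmetry with the liver).

# Numerical choices

* **Distance transforms** are exact Euclidean (two-pass separable
  parabolic envelopes) with anisotropic mm spacing.
* **Erosion by a physical depth** thresholds the distance transform at
  `depth + 0.25 * pixel`: the continuous boundary lies beyond the last
  foreground pixel center by about half a pixel for straight edges, but
  the minimum over background centers pulls the effective offset to
  about a quarter pixel for curved boundaries.  The constant was fixed
  by matching eroded disk and square areas to their closed forms on
  analytic rasters (errors then < 1% at 1 mm pixels) and is documented
  here rather than exposed, since it is a property of the lattice, not
  of anatomy.
* **Connectivity** is 8 for components and 4 for hole filling
  (configurable); both implemented with explicit flood fills so the
  convention is guaranteed.
* **Normalization** of the ILT response divides by the global maximum;
  an all-zero response passes through.  Min-max normalization would
  differ only when the minimum is positive, which does not occur in
  practice because air is present in every slice.
* **Gaussian fits** use Levenberg-Marquardt least squares on histogram
  counts (start: max count, median, SD); a zero-variance sample returns
  its value directly; non-convergence raises an error carrying n and SD.
* **HU values** are clamped to [-1024, 3071] at phantom rendering, and
  `CTSlice` validates finiteness, range and positive spacing.

# The phantom generator

`makePhantom()` renders parametric single-slice phantoms with
ground-truth labels: an elliptical body with SAT ring and muscle wall
(optional anterior gap), cavity with organs and visceral fat, spine with
cortical shell and trabecular core, paraspinal muscles and a perispinal
fat ring (abdomen); plus liver, spleen and stomach at the liver station
(liver attenuation sweepable over 0--60 HU); two thighs with SAT, a
1-px fascia lata over a subfascial fat band, muscle, intermuscular fat
islands and cortical bone with fatty marrow.  Tissues get additive
Gaussian noise (SD 10 HU for soft tissue, 5 for air and table) around
means placed inside their bands (fat -95, muscle 45, organs 35, liver 50,
marrow -80, cortical bone 1200 HU).  `makeEnsemble()` jitters geometry
uniformly within stated half-widths to stand in for a multi-subject
study; jitter ranges are constrained so the anatomy stays consistent
(e.g. the thighs cannot overlap).

Default problem sizes: 192 x 192 px at 2 mm spacing, 50-phantom
training and evaluation ensembles for the abdomen, 25 reference
segmentations for the liver atlas, 7 levels of the liver sweep -- the
same set sizes as the study design the package mirrors, at a pixel
resolution coarse enough to keep a full validation run in minutes.

What the phantoms do *not* emulate: partial-volume mixing at tissue
boundaries (labels are crisp), beam hardening, streak and ring
artifacts, anatomical texture (organs are uniform ellipses), fascia
invisibility (the real fascia lata is visible in only ~5% of images;
the generator can disable it), and focal or heterogeneous fatty liver.
Passing the phantom suite therefore demonstrates the geometric and
statistical correctness of the algorithms under their stated
assumptions -- not clinical-grade performance on patient data, where
boundary attenuation is graded and priors are imperfect.  The published
real-data figures (VAT/SAT Dice around 0.97--0.99, a few percent area
overestimation, SFAT Dice near 0.64) are the realistic expectation; the
phantom analogs are intentionally easier and are used to catch
regressions, not to claim clinical accuracy.

# Known limitations

* No spleen detector: spleen exclusion relies on the shape prior
  down-weighting the left side.
* Heterogeneous/focal fatty liver is not detected; sampled-attenuation
  thresholding can bias such cases, which motivates visual screening in
  large studies.
* The SAT definition follows the automated convention (adipose outside
  the ILT cavity); a manual outer-wall-contour reference differs by the
  fat within the wall itself.
* DICOM support covers uncompressed single-frame little-endian files
  only; volumetric (3D) segmentation is out of scope.
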