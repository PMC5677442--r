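---
title: "Detecting termite mounds in UAV hyperspectral imagery: methods"
author: "moundscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting termite mounds in UAV hyperspectral imagery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moundscan)
```

## The detection problem

Pre-existing termite mounds in arid Australian rangeland present a
characteristic signature from the air: an eroded bare-soil core, oval or
diamond shaped in plan view, with vegetation density near zero inside and a
conspicuous ring of bright grass just outside, fed by the nutrients washed
off the mound. Neither layer alone is diagnostic — bare soil and bright
grass each occur all over a scene — but their tight spatial pairing is.
`moundscan` implements a detector built on exactly that idea, operating on
VNIR (385–1000 nm) hyperspectral cubes such as those from a pushbroom UAV
sensor at roughly 4.7 cm/pixel ground sample distance (GSD).

The pipeline is:

1. **Cube input and ROI cropping** — ENVI-style cubes (`read_cube()`), a
   register of rectangular pixel windows (`crop_roi()`).
2. **Band pre-cleaning** (`preclean_cube()`) — one grayscale morphological
   closing with a 3×3 rectangle, per band, to fill dark speckle.
3. **Reflectance recovery** (`to_reflectance()`) — per-pixel division by a
   constant white-reference illuminant spectrum.
4. **Material classification** — a material spectra library built once by
   deterministic-annealing clustering (`cluster_materials()`), then a
   per-pixel linear SVM against that library (`classify_cube()`), and
   extraction of the two mound-diagnostic binary layers
   (`extract_layers()`).
5. **Two-layer detection** (`detect_mounds()`) — condition the layers,
   gate on their overlap, shape-filter soil contours against mound
   templates by Hu-moment matching, and confirm each candidate with a
   nearby grass contour.
6. **Evaluation** (`match_detections()`, `aggregate_report()`) — TP/FN/FP
   tallies and the accuracy score TP/(TP+FN+FP).

## Reflectance model

Reflectance is the plain ratio of radiance to the white-reference intensity,
band by band. The white spectrum is taken as constant across the scene
(dynamic illuminant estimation is out of scope), is linearly interpolated
onto the cube's wavelength grid when the two differ, and extrapolation is
refused. Ratios are clipped at a configurable ceiling (default 2.0): on
specular facets radiance can exceed the panel signal, and an unbounded
feature occasionally dominates the classifier's feature space. No
dark-current subtraction is modelled; inputs are assumed radiometrically
calibrated by the sensor vendor's software.

## Material library by deterministic annealing

The library is clustered once from a demonstrative reflectance scene with
`cluster_materials()`. The algorithm is squared-Euclidean deterministic
annealing: soft assignments $p(c\mid x)\propto \pi_c\,e^{-\lVert x-c\rVert^2/T}$
are alternated with centroid updates while the temperature $T$ anneals from
`t_max = 0.02` down to `t_min = 0.00025` by the cooling factor 0.8. Those
values, the cluster cap of 10, the split threshold of 0.8 and the cap of 5
materials associated per pixel are the operating point the field library
was built with, and they are the package defaults (`da_params()`).

Two details are under-determined by that parameter list and were fixed as
follows:

* **Split criterion.** In Rose-style annealing a cluster becomes unstable
  below its critical temperature $T_c = 2\lambda_{\max}$, with
  $\lambda_{\max}$ the largest eigenvalue of the cluster covariance. The
  split threshold is read as a conservative factor on $T_c$: a cluster is
  duplicated (with a small seeded perturbation along its principal axis)
  when $T < 0.8 \cdot 2\lambda_{\max}$. This reading makes the printed
  schedule self-consistent: with per-band noise of s.d. ≈ 0.01 the
  noise-floor critical temperature ($\approx 2\times10^{-4}$, times 0.8)
  sits just below `t_min`, so clusters split on real material structure but
  not on noise.
* **Per-pixel association cap.** `max_materials_per_pixel` truncates each
  pixel's posterior to its top 5 clusters during annealing. Final output is
  hard: the classification stage produces one label per pixel, because the
  detector consumes binary layers only.

Coincident duplicate centroids (splits attempted above the true critical
temperature) are re-merged, so a uniform scene yields a single material
rather than an error.

## SVM classification

The library carries a single signature per material, which is not a
training set. Each signature is therefore augmented with 200 multiplicative
Gaussian jitters (`spectrum * (1 + N(0, 0.02))` per band), features are
standardised per band (with a floor on near-zero band variances), and a
linear-kernel SVM with cost 1 is fitted via libsvm (`e1071`), which handles
multiclass problems by one-vs-one voting. Linear margins suffice here: the
library spectra are smooth and well separated over three wavelength windows
(see below), and the jitter cloud is tight. All settings are arguments of
`train_classifier()`.

## The two-layer detector

`detect_mounds()` implements the segmentation stage on the "Eroded Soil"
and "Light Grass" masks:

1. **Conditioning.** Soil: 3×3 median (majority) filter, then one binary
   closing with a 3×3 rectangle. Grass: median only — the asymmetry is
   deliberate; the grass layer feeds proximity tests, not shape analysis,
   and closing would thicken it.
2. **Overlap gate.** The conditioned soil layer is dilated twice with the
   3×3 elliptical element (at this size, the 4-connected cross), and ANDed
   with the grass layer. If the mean of that mask is zero — the layers
   touch nowhere — the ROI is declared mound-free and contour analysis is
   skipped entirely.
3. **Soil contours.** Outer borders of 8-connected components, traced in
   the Suzuki–Abe border-following style. Contour geometry is polygonal:
   area by Green's theorem on the polygon through pixel centres, perimeter
   as arc length, centroid from the polygon moments, and the radius of the
   exact minimum enclosing circle.
4. **Shape filter.** Each soil contour's seven Hu invariants $h_1..h_7$ are
   mapped to signed-log space, $m_i = \mathrm{sign}(h_i)\log_{10}|h_i|$,
   and compared against a library of binary mound templates (ovals and
   diamonds at several aspect ratios) by
   $\mathrm{ratio} = \sum_i |1/m_i^S - 1/m_i^T|$, taking the minimum over
   templates. A contour survives if that ratio is at most 0.15 and its
   perimeter at least 10 px.
5. **Pairing.** A surviving soil contour becomes a detection if some grass
   contour satisfies all of: centroid distance $d \le 1.2\,\mathrm{rad}$
   (rad = soil enclosing radius); grass perimeter at least the soil
   perimeter, or at least 0.8 of it; and minimum point-to-point distance
   (ILD) at most 2.5 px. Because $P_{gc}\ge P_{sc}$ implies a proportion of
   at least 1, the perimeter clause reduces to the 0.8 proportion test;
   both conditions are nonetheless evaluated and reported per detection. A
   soil contour with several qualifying grass partners yields one
   detection listing all of them.

All thresholds live in `detection_params()` and are raster-space pixels;
they are not rescaled by GSD.

### Numerical choices

* **Threshold directions.** The keep/discard sense of the shape filter is:
  *keep* when the ratio is small and the perimeter large. Lower ratio means
  closer shape; the thresholds exist to discard non-mound-like contours.
* **Log floor.** $\mathrm{sign}(h)\log|h|$ is undefined at $h = 0$, and for
  near-symmetric shapes the high-order invariants are numerically zero
  with unstable sign. Terms with $|h_i| \le 10^{-5}$ (for either shape) are
  excluded from the ratio — the exclusion level of the classical
  moment-matching implementations. With a much smaller floor, sign flips in
  $h_5..h_7$ of rasterised ovals inject spurious ~0.1-magnitude terms and
  destroy the rotation invariance the matcher exists to provide.
* **Hole borders.** Grass rings can be closed annuli; the part of a ring
  that approaches the soil core is its inner rim. `find_contours()`
  therefore traces inner (hole) borders as well, and the detector uses
  them for the grass layer. Soil contours remain outer-only: mound cores
  are filled regions.
* **Degenerate contours.** Components with fewer than three boundary
  points or zero polygon area carry no moments; the shape filter discards
  them via the perimeter gate without attempting Hu computation.
* **Ties.** The arg-min template name is recorded with each detection; the
  reported pairing distances are those of the nearest qualifying grass
  partner.

### A note on conditioning and idempotence

Grayscale closing is idempotent and extensive, and the package's replicate
border padding preserves both properties up to the image edge; running
`preclean_cube()` twice is exactly running it once. The *soil conditioning*
composite (median, then closing) is not mathematically idempotent: a 3×3
median on a binary mask is the majority filter, and majority dynamics churn
at sharp convex corners. In practice conditioned oval cores are stable
under a second pass, while diamond cores can shed or regain a tip pixel.
This is a property of the operator as specified (the same holds for the
classical smoothing implementations), documented here rather than patched,
since the detector applies conditioning exactly once.

## Synthetic scenes and ground truth

Field imagery is not distributable, so the package ships a generator
(`generate_scene()`) that emulates the surveyed scenery and provides exact
truth:

* **Mounds** are painted as eroded-soil cores — ovals or diamonds, rotated —
  ringed by light grass. Default core semi-axes come from the surveyed mean
  bounding rectangle of 1.951 m² at the configured GSD (4.7 cm/px default,
  aspect ratio 1.25, ≈ 17 × 13 px semi-axes); the ring is 3 px wide.
  Overlapping mounds are refused.
* **Background** is a seeded Voronoi tessellation of the remaining eight
  materials — contiguous patches, not i.i.d. pixels, mimicking bush and
  grass patches.
* **Spectra** (`default_spectra()`) are ten smooth synthetic reflectance
  curves in [0, 1] whose inter-material contrast is concentrated in the
  540–700, 720–800 and 924–1000 nm windows, where field spectra of soils
  and vegetation differ most; differences elsewhere are small. The
  rendered cube is reflectance times a smooth positive synthetic
  illuminant, so `to_reflectance()` inverts the rendering exactly.
* **Degradations:** per-band Gaussian blur; per-pixel Gaussian noise
  (reflectance-scaled); and a smooth sinusoidal displacement field of
  configurable amplitude applied to the label raster by inverse warping.
  The displacement wavelength is drawn from 30–80 px — comparable to the
  mound footprint — so the field shears and squeezes shapes locally
  rather than translating them rigidly; no quantitative distortion model
  for the field imagery exists, so the amplitude is a free simulation knob.

Scenes are bit-reproducible under their seed. What the generator does *not*
model: physically based radiative transfer, sensor point-spread functions
beyond Gaussian blur, mixed pixels at material boundaries beyond blur,
shadows cast by relief, or seasonal variation of the grass ring. Passing
the closure tests below therefore demonstrates internal consistency of the
pipeline, not field-grade accuracy.

## Evaluation

Truth matching is greedy one-to-one by ascending centroid distance, with a
default match radius of 1.5× the largest truth core semi-axis — a proxy
for the visual co-location a human scorer applies. The accuracy score is
TP/(TP+FN+FP); the report writer emits per-ROI rows plus a pooled `Total`
row (accuracy on summed counts, which is not the mean of per-ROI
accuracies) and a `Proportion` row (TP, FN, FP as percentages of all true
mounds, to one decimal). The package ships a 25-ROI example register
(`inst/extdata/roi_counts.csv`, 119 mounds) whose pooled accuracy is 68.0%
and proportions 73.1 / 26.9 / 7.6%.

## Validation bench and problem sizes

Two bench functions drive the routine end-to-end checks:

* `closure_benchmark()`: 20 noiseless, blur-free, undistorted scenes of
  224 × 224 px × 30 bands with 3–6 mounds each. Expected behaviour, and
  what the tests assert: the SVM label map equals the generator's material
  raster on every pixel, and detection attains recall 1.0 with zero false
  positives at default thresholds.
* `distortion_benchmark()`: detection-only recall (on the generator's
  exact material layers, isolating the shape analysis from classification)
  over 20 seeds per distortion amplitude in {0, 1, 2, 4} px, with common
  random numbers across amplitudes. Mean recall is non-increasing in the
  amplitude — distorted cores stop matching the oval/diamond templates —
  which reproduces, qualitatively, the main failure mode observed on field
  imagery.

These sizes keep the full suite comfortably fast while leaving each scene
large enough to hold several survey-scale mounds at 4.7 cm/px.

## Known limitations

* Thresholds are hand-set constants; no learning or optimisation of them
  is provided (deliberately out of scope).
* The detector is resolution-dependent: perimeter and distance gates are
  in raster pixels, so cubes at a very different GSD need re-tuned
  parameters.
* Soil conditioning is not strictly idempotent at sharp diamond tips (see
  above).
* The matcher compares outer-contour shape only; two materials with
  mound-like adjacency but non-mound shapes at matching scale would fool
  it, and heavily distorted true mounds are missed by design of the shape
  gate.
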