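---
title: "Methods: threshold segmentation and connectomics of osteocyte networks"
author: "osteoconnect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold segmentation and connectomics of osteocyte networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoconnect)
```

## The problem

Osteocytes are the most abundant bone cells. Each sits in a lacuna in the
mineralised matrix and extends dozens of thin dendritic processes through
canaliculi, forming the lacunocanalicular network (LCN) that carries
mechanosensation and signalling through bone. Degeneration of this
network — fewer cells, fewer connections, shorter and blunted
dendrites — accompanies ageing and osteocyte-targeted genetic lesions.

Quantifying the network from confocal laser scanning microscopy (CLSM) is
laborious: cell bodies are bright, roughly elliptical blobs, but the
processes are only 1.5–3 px wide at a typical digital resolution of
150 nm/px, close to the ~450 nm diffraction limit (~3 px). This package
implements a complete 2D analysis chain for such images:

1. **Threshold segmentation** of greyscale scans into background,
   osteocyte, and dendrite classes (Otsu- or Canny-cored pipelines).
2. **Connectomics**: conversion of a 3-class mask into a graph whose
   nodes are osteocytes and whose edges are dendritic connections, with
   per-image network metrics.
3. **Evaluation**: per-class Dice and IoU against reference masks.
4. **Dendrite regularisation utilities**: an inverse component-size
   penalty scoring mask fragmentation, and label dilation.
5. **Group comparison**: two-sided Mann–Whitney U tests and a
   percentage-change protocol.
6. A **synthetic-scene generator** that produces seeded, ground-truthed
   imitations of such scans, so every stage can be validated offline.

## Segmentation pipeline

Both pipelines share their pre- and post-processing and differ only in
the core step:

* **Smoothing.** Gaussian filter with $\sigma = 2$ px (discrete kernel
  truncated at $3\sigma$, reflective borders, output rounded back to the
  0–255 integer scale).
* **Candidate split.** A manual binary threshold of 70 (0–255 scale)
  separates the image into osteocyte candidates (≥ 70) and a dendrite
  candidate band below it. A second threshold removes low-intensity
  noise from the dendrite band; its published value is not available, so
  the package defaults to 30 (configurable). The published description
  of which band is which reads the other way around
  ("the lower end being osteocytes"); because cell bodies are by far
  the brightest structures in these stains, the package defaults to
  bodies-high and provides `invert_split = TRUE` to run the literal
  reading.
* **Core step.**
    * *Otsu*: the threshold maximising between-class intensity variance
      is computed on the smoothed image by exhaustive search over all
      255 splits (ties resolved to the lowest threshold) and clamped to
      a minimum of 80. Its foreground — bright body-level pixels — is
      subtracted from the dendrite candidate band. The parameter pair
      written as "(80, 255)" is interpreted as (lower clamp, foreground
      write value); a threshold of at least 80 cannot select pixels
      inside a [30, 70) band, so the clamp necessarily acts on the
      global image rather than on the band itself.
    * *Canny*: standard Canny (Sobel gradients, 45°-quantised
      non-maximum suppression with an asymmetric tie-break so a
      symmetric two-pixel plateau keeps one pixel, hysteresis with
      thresholds 70/220 on the L2 gradient magnitude). Whether the edge
      map should be intersected with the candidate band is not
      specified; the default intersects (`canny_restrict = "band"`).
* **Refinement.** The dendrite mask is closed with a 3×3 square kernel
  and pixels claimed by both classes are removed from the dendrite mask
  (osteocyte wins). The osteocyte class is fixed before the core step,
  so the Otsu and Canny pipelines agree on it exactly.

The pipeline contains no randomness: identical inputs and parameters
give identical masks.

## Connectomics

The two foreground classes are separated and dilated — osteocytes with
the discrete ellipse inscribed in a 4×4 box, dendrites with a 2×2 cross
element — to merge fragments that should be one entity and to create the
pixel overlap used for contact detection. Even-sized elements have no
centre pixel; they are anchored one pixel right/below the geometric
centre so that dilation never drops a pixel and growth is biased half a
pixel towards the top-left (frozen in a fixture test).

Connected components (8-connectivity by default, so diagonally touching
dendrite traces are one process) of the dilated osteocyte mask are the
graph nodes. Each dendrite component is classified by the set of
osteocyte components it overlaps: ≥ 2 contacts yield one connection per
contacted pair (a pairwise clique — the component itself contains no
osteocyte pixels, so each pair has an independent route not passing
through another osteocyte, and routes via intermediate osteocytes are
never added); exactly 1 contact is a dead end of that node; 0 contacts
is an orphan fragment. Two distinct components joining the same pair
count as two connections (routes, not neighbours); `unique_partners`
switches to degree-style counting. Dead ends are counted per component
by default, or per free skeleton endpoint with
`deadend_mode = "endpoint"`.

Measurements are taken on the **original** (undilated) dendrite pixels
under each dilated component, so the merging dilation does not inflate
them:

* **Length**: the mask is thinned to a 1-px skeleton (Zhang–Suen) and
  path length accumulated along it with axial steps of 1 px and diagonal
  steps of $\sqrt 2$ px. A connection's length is the skeleton path
  between its two osteocyte contact points, completed at both ends by
  the straight-line gap from the skeleton terminus to the
  contact-region centroid (thinning erodes line ends by a few pixels;
  the completion restores them). On generated curved dendrites this
  estimator is within ~7% of the true arc length.
* **Diameter**: $2\,\overline{\mathrm{EDT}} - 0.5$ px, where
  $\overline{\mathrm{EDT}}$ is the Euclidean distance transform averaged
  over the skeleton. The −0.5 px is a discretisation correction: the EDT
  measures to background pixel centres and therefore overshoots the mask
  boundary by half a pixel per side (−1 px), while the skeleton of
  even-width runs sits half a pixel off the centreline (+0.5 px on
  average over odd/even widths).

The six per-image summary metrics are: node count, mean dead ends per
node, mean connections per node ($2|E|/n$), mean connection length, mean
connection diameter, and the mean diameter over **all** dendrite
components (connections, dead ends and orphans) — whether the
network-wide diameter should include non-connection fragments is not
specified; including them is the default here.

## Evaluation metrics

Per class $k$, prediction $P$ and ground truth $G$ are compared
one-vs-rest with

$$\mathrm{DSC} = \frac{2|P \cap G|}{|P| + |G|}, \qquad
  \mathrm{IoU} = \frac{|P \cap G|}{|P \cup G|}.$$

When both masks are empty the score is defined as 1 (agreement that
nothing is present; `empty_value = NaN` flags it instead). Mean IoU
averages the osteocyte and dendrite classes, excluding background by
default to match two-class reporting; `dice_overall` is the Dice of the
union of foreground classes, a class-agnostic localisation summary
(the single-number "DSC" convention is not defined in the source
description; this definition is the package's choice). Batch evaluation
reports both the per-image mean and the pooled-pixel reduction, since
the published headline accuracies do not state which was used.

## Dendrite regularisation utilities

The inverse component-size penalty is the discrete form of a
training-time regulariser that discourages fragmented dendrite
predictions:

$$\mathcal{P}(M) = \lambda \sum_{c \in \mathrm{CC}(M)} \frac{1}{|c|}.$$

Merging fragments of sizes $a$ and $b$ strictly lowers it, since
$1/(a{+}b) < 1/a + 1/b$. The published pseudocode does not state a
normalisation; `normalize = "per_component_mean"` divides by the number
of components, and the default is no normalisation. Label dilation
(2×2 or 3×3 square kernels) thickens under-annotated thin dendrites,
resolving collisions osteocyte-first.

## Group comparison

Per-image metrics of two cohorts are compared with a two-sided
Mann–Whitney U test at $\alpha = 0.05$. For combined $n \le 20$ without
ties the exact permutation null is used (via the exact Wilcoxon
distribution, identical to full enumeration in that regime); otherwise
the normal approximation with tie and continuity correction. U is
reported as $\min(U_x, U_y)$. Sidedness is not stated in the source
description; two-sided is the package default, and no multiple-testing
correction is applied (per-metric reporting), with Holm available.
Percentage change is $100\,(\bar x_{\mathrm{ref}} - \bar
x_{\mathrm{other}})/\bar x_{\mathrm{ref}}$ — positive values are
decreases relative to the reference group — and is reported
descriptively, without a test, when comparing two single summary values.

## The synthetic-scene generator

No public reference dataset of labelled osteocyte CLSM scans exists, so
the package ships a generator that emulates the imaging regime: a
500×500 px field at 150 nm/px; elliptical bodies with semi-axes
10–20 px (body axes 3–6 µm, typical of osteocyte lacunae at this
resolution); dendrites as smoothed random polylines (2–4 control
points, so curvature exercises the skeleton-length estimator) stroked at
widths 1.5–3 px with anti-aliased coverage thresholded at 0.5 for the
mask; dead-end dendrites launched at stratified angles around each body
(canaliculi radiate roughly evenly; independent angles produce
unrealistic bundles); a Gaussian PSF of $\sigma = 1.5$ px (≈ 450 nm
FWHM); additive Gaussian noise; a linear illumination gradient; and
optional artefacts (a transiting blood vessel, shrunken osteocytes)
rendered into the image but labelled background, acting as unlabelled
distractors exactly as in real scans.

Study-condition presets:

* `young_scene_params()`: mean 7 osteocytes per field and 20.9 dead ends
  per node (per-image means of manually labelled validation data for
  this regime), connection probability 0.8 within 260 px.
* `aged_scene_params()`: density ×(1 − 0.3803) and connection
  probability ×(1 − 0.433) — the manually measured ageing decreases —
  plus a dead-end rate ×1.3 and dead-end lengths ×0.75. The last two
  magnitudes are direction-only in the source material; the factors are
  this package's fixed choices.
* `sparse_scene_params()`: a validation preset (5 well-separated bodies,
  few dead ends, overlap-avoiding placement, no blur/noise/gradient) on
  which the connectomics graph recovered from the true mask matches the
  generated ground truth exactly.

Intensity statistics (background 10, dendrites 90, bodies 220, noise
SD 5, 10% illumination fall-off) are plausible-value choices — the
source material reports no SNR or background levels. Scenes are fully
reproducible: identical parameters and seed give byte-identical images,
masks and graphs; cohort generation derives per-scene seeds from one
master seed.

**What passing tests do and do not show.** The generator produces
clean-edged ellipses, single-scale Gaussian blur, spatially white noise
and (in the sparse preset) non-crossing dendrites. Real scans add
out-of-plane structure, stain heterogeneity, anisotropic PSFs and
touching cells. Ground-truth recovery and quality floors on synthetic
scenes therefore validate the *implementation* of the measurement chain,
not its accuracy on real bone; published per-class accuracies on real
data (bodies far easier than dendrites) motivate the ordering of the
repo's quality bars (osteocyte DSC ≥ 0.8, dendrite DSC ≥ 0.4 on
low-noise scenes), not their values.

## Numerical choices and degenerate inputs

* Otsu on a constant image is an error (degenerate histogram); the
  segmentation pipeline short-circuits constant images to "no dendrite
  foreground removed".
* Otsu ties: lowest threshold among variance maximisers.
* Closing is computed on a virtually extended canvas, so it is extensive
  (never removes mask pixels) up to the image border and returns
  already-closed shapes unchanged.
* Both-empty Dice/IoU = 1 by convention, flaggable.
* A zero-node graph yields all-zero metrics with a warning; a graph with
  nodes but no connections reports 0 for the connection means.
* A component whose skeleton collapses to a single pixel is assigned one
  pixel of length; measured diameters are floored at half a pixel.
* Edge lengths fall back to the component-level geodesic when the
  merging dilation bridged originally disconnected fragments.
* Unreachable node pairs report `Inf` hops.
* Infeasible body packings (too many bodies for the field at the minimum
  separation) error out after bounded rejection-sampling retries.

## Problem sizes used in the shipped validation

The test-suite and the acceptance script run entirely on synthetic
scenes: 20 sparse 500×500 scenes for ground-truth recovery, 20
young-preset scenes for the segmentation quality floor, 100
30-vs-30-image cohort replicates (ground-truth graphs only, no
rendering) for discrimination, 1000 null simulations at n = 15/group
for type-I calibration, and a 2-scene-per-group 256 px pipeline run for
byte-level determinism. These sizes were chosen to keep a full
validation run in the minutes range on a single CPU while leaving the
statistical checks well-powered.

## Known limitations

* 2D only: no z-stack handling, consistent with the 2D scope of the
  source analysis; 3D reconstruction is future work.
* The M1/M2 literature replicas (low-pass + adaptive threshold;
  thinning-based) are out of scope: their parameters were tuned to a
  private dataset and never published.
* No deep-learning inference; the component-size penalty is provided as
  a discrete evaluator, not a differentiable loss.
* The generator does not model photobleaching, PSF anisotropy or stain
  normalisation issues.
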