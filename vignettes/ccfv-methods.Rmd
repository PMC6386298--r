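---
title: "Quantifying choriocapillaris flow voids around geographic atrophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying choriocapillaris flow voids around geographic atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccfv)
```

## The measurement problem

Geographic atrophy (GA), the late stage of dry age-related macular
degeneration, enlarges over time, and the choriocapillaris (CC) — the
capillary bed directly under the retinal pigment epithelium — shows flow
impairment not only beneath the atrophic patch but in the surrounding
tissue. On en-face OCT angiography (OCTA), this impairment appears as
*flow voids*: pixels whose decorrelation signal falls below a local
threshold. `ccfv` quantifies the peri-lesional flow-void burden and relates
it to how fast the lesion grows.

Per eye the pipeline computes:

* **FV_OUT** — flow-void percentage over all non-lesion pixels;
* **FV_500** — over the *para-atrophy region*, the ring of tissue within
  500 µm of the lesion edge;
* **FV_1000** — over the *peri-atrophy region*, 500–1000 µm from the edge;
* **ΔFV = FV_500 − FV_1000** — the local excess of impairment right at the
  lesion margin, which self-corrects for each eye's global void level and
  for the physiological eccentricity gradient of the CC;
* **yGR = (√GA_II − √GA_I) / FU** — the yearly growth rate after
  square-root area transformation (mm/yr), which removes the dependence of
  raw area growth on baseline lesion size: a disc whose edge advances at
  speed $v$ has $d\sqrt{A}/dt = \sqrt{\pi}\,v$ for any radius.

At the cohort level the package computes Pearson correlations of yGR with
each flow-void measure, two-grader ICC for repeatability, and generalized
estimating equations (GEE) with patients as clusters — first a univariable
screen over the candidate covariates, then a multivariable model over the
screened-in ones.

## Image pipeline

**Normalization.** Images load as `[0, 1]` grayscale (8/16-bit sources are
divided by their nominal maxima), so every downstream constant is
bit-depth independent.

**Shadow compensation.** Drusen attenuate the OCT beam, darkening both the
structural CC slab and the angiogram beneath them. Following the usual
inverse-transform strategy, the structural image is inverted on the
normalized scale ($1 - S$), smoothed with a 3 × 3 Gaussian kernel to
suppress speckle, and multiplied into the flow image. We realize the
"3 × 3 Gaussian" as σ = 0.85 px truncated to 3 × 3 and renormalized — the
common discrete approximation; both the kernel size and σ are
configurable (`compensation_params()`). Because the multiplier is the
*inverted* structure, dark (shadowed) regions receive a proportionally
larger boost. The multiplication is not an exact deconvolution of a
multiplicative shadow — for a shadow factor $w$ and unshadowed structural
level $s_0$ the residual gain is $w\,(1 - w s_0)/(1 - s_0)$, not 1 — but
the residual is smooth and local, and the local-adaptive binarization that
follows is insensitive to it; the synthetic-data tests verify that void
fractions under drusen land within a couple of percentage points of their
shadow-free reference. The product is min–max rescaled to `[0, 1]` by
default; whether the original workflow rescaled before thresholding is not
documented, so both behaviours are supported (`rescale = FALSE` keeps the
raw product) and the choice is recorded in the run manifest. If the
product is constant the rescale is degenerate and the flow image is passed
through unchanged.

**Binarization.** Flow voids are segmented with the Phansalkar local
threshold, designed for low-contrast images:

$$t = m\left(1 + p\,e^{-q m} + k\left(\frac{s}{R} - 1\right)\right)$$

with $m$, $s$ the mean and population SD over a circular window (ImageJ
convention) of radius 15 px on the native 1024-px grid (≈ 88 µm), mirror
padding at borders, and the original constants $k = 0.25$, $R = 0.5$,
$p = 2$, $q = 10$ (only the radius is typically reported; the constants
match the ImageJ Auto Local Threshold defaults). A pixel is a void iff its
value is strictly below $t$. The implementation is a direct circular-window
scan in C++; the test suite holds it pixel-exactly equal to a brute-force
per-pixel oracle, and a constant image yields the closed-form threshold
$0.5(1 + 2e^{-5} - 0.25) \approx 0.3817$ and zero voids.

## Regions, areas, distances

Regions derive from the exact Euclidean distance transform of the
background, measured from the union of all lesion foci (pixel centres,
0-based indices; `EBImage::distmap` supplies the transform). Ring
membership uses half-open intervals — para: distance ∈ (0, 500] µm, peri:
(500, 1000] µm — so no pixel is double-counted, and because distance is
taken from the union of foci, the rings of adjacent foci abut without ever
overlapping a lesion. FV_OUT is computed over *all* non-lesion pixels by
default (the rings are part of "outside"); the variant that excludes the
rings (`fv_out_mode = "exclude-rings"`) is computed alongside and reported
as `FV_OUT_beyond`, since published descriptions do not always say which
was used.

Foci are labeled with 8-connectivity (the ImageJ particle default). The
fovea distance is the unweighted mean over foci of the centroid-to-fovea
distance. Eyes whose lesion touches the outermost pixel ring at either
visit are flagged and excluded from growth statistics — their true extent
is unknowable from the scan. Negative growth (shrinking masks) is retained
and visible in yGR rather than clamped; clamping would bias cohort means.

## Statistics

* **Pearson** correlations use the exact t transform for two-tailed
  p-values.
* **ICC** defaults to ICC(2,1) — two-way random effects, absolute
  agreement, single measures — because two fixed graders measured every
  eye and systematic offsets between them should count as disagreement;
  ICC(3,1) is available. Confidence intervals use the McGraw–Wong F
  formulas computed from the two-way mean squares.
* **GEE** uses a Gaussian family with identity link, an exchangeable
  working correlation (the natural choice for 1–2 eyes per patient), and
  robust sandwich standard errors; estimation is iterated generalized
  least squares with moment re-estimation of the intra-cluster
  correlation. With singleton clusters the working correlation vanishes
  and the estimates coincide with OLS — a property the tests pin to 1e-6.
  Because the uncorrected sandwich is anti-conservative with only a few
  dozen clusters (simulation at 23 patients puts the nominal-5% screen
  near 11–12% rejection under the null), the default inference applies
  the Mancl–DeRouen bias correction to the meat of the sandwich and
  refers Wald statistics to a t distribution on clusters − parameters
  degrees of freedom, which restores near-nominal calibration; the plain
  sandwich with a normal reference remains available via `se = "robust"`.
  Point estimates are identical under either choice.
  The univariable screen admits covariates at p < 0.05 into the
  multivariable model. Because ΔFV is an exact linear combination of
  FV_500 and FV_1000, a screen that admits all three produces a singular
  joint design; the multivariable stage therefore enters covariates in
  order of univariable strength and drops any candidate aliased by those
  already entered, recording the drop in the report. No multiplicity
  correction is applied across the seven candidates, mirroring the usual
  screen-then-model reporting; this is a known weakness of that design,
  not a feature.

## The synthetic cohort generator

Real raw OCTA volumes are rarely redistributable, so validation runs on a
generator whose defaults encode the cohort being emulated: 23 patients
(bilateral with probability 10/23, ≈ 33 eyes), follow-up 1.31 ± 0.2 years
floored at 1 year, age 84.67 ± 6.42, baseline lesion areas log-normal
about a 0.8 mm² median (capped at 8 mm²), lesion centroids placed
|N(0.86, 0.54)| mm from the fovea, a base void fraction of 0.42 at the
fovea, and an eccentricity gradient of −0.008 void fraction per 500 µm.

Each eye is built as follows:

1. **Void-probability field.** Base fraction + eccentricity gradient +
   a peri-lesional excess drawn from `ring_excess_range` (default
   U[0, 0.10]) that holds its full value from the lesion edge out to
   500 µm and tapers linearly to zero at 1000 µm. Published data
   constrain only the two ring means (FV_500 > FV_1000 > FV_OUT), not the
   radial profile, so the plateau-then-taper shape is a modelling
   stand-in, not a claim about biology.
2. **Granular texture.** White noise band-pass filtered by a difference
   of Gaussians at the CC lobule scale (grain 25 µm) is rank-transformed
   to uniform and thresholded against the probability field, so the
   planted void fraction equals the field value exactly while voids form
   spatially coherent grains. Void pixels take flow level 0.30, perfused
   pixels 0.85, plus N(0, 0.05) pixel noise and a smooth low-order
   illumination field (± 5%) on the angiogram.
3. **Drusen shadow.** Poisson-scattered discs (3 per mm², radii
   30–80 µm) darken both channels multiplicatively by 30% with
   Gaussian-feathered edges; the structural channel is otherwise bright
   and uniform (0.85 + noise). Applying the illumination field to the
   flow channel only keeps the structural inversion from amplifying it —
   inverting a bright channel turns small common-mode variations into
   large relative gain swings, which is also why real-world compensation
   works best when the structural slab is clean.
4. **Growth.** The edge speed is `growth_coupling × excess` (default
   4 mm/yr per unit excess) plus N(0, 0.02) noise truncated at zero; the
   follow-up mask is the baseline mask dilated isotropically by
   speed × FU via the exact distance transform. Lesions are 1–3 ellipses
   (p = 0.7/0.2/0.1) with axis ratio U[0.6, 1]; eyes whose lesion
   reaches the border at either visit are flagged `border_truncated`.
5. **Output.** Images are quantized to 16-bit before use so in-memory and
   on-disk analyses agree bit-for-bit. Every eye consumes an RNG stream
   derived from `(seed, eye index)`, so cohorts are reproducible and
   individual eyes can be regenerated independently.

Ground truth per eye records the probability-field means per region, the
ring excess, the edge speed, areas, and focus centroids.

**What the generator does not emulate:** OCTA decorrelation physics and
projection artifacts, motion artifacts, real drusen morphology (it uses
discs), registration error between visits, and segmentation error in the
GA masks (masks are exact). Passing the recovery tests therefore shows the
*measurement chain* is faithful — planted fractions and growth rates come
back out — not that the pipeline is robust to every artifact of real
scans.

## Numerical choices and degenerate inputs

* Mirror (symmetric) padding for all windowed operations; documented and
  shared between the fast path and the test oracles.
* Population (not sample) SD inside the Phansalkar window.
* Exact Euclidean distance transform; ring intervals half-open; distances
  between pixel centres.
* Empty regions are hard errors naming the region; empty masks cannot
  build regions; a follow-up time ≤ 0 is an error; a constant compensated
  product skips the degenerate min–max rescale.
* The GEE intra-cluster correlation estimate is clamped to
  `[-1/(max cluster size - 1) + 1e-6, 0.99]`; iteration stops when the
  coefficient step falls below 1e-10 relative.

## Problem sizes used in the checked-in experiments

The test suite and acceptance script choose grid sizes per experiment: the
analytic-geometry and square-root-transform checks run at the native
1024-px grid, where pixelation error is far below the stated tolerances;
cohort-level recovery experiments run at 256 px with the binarization
radius rescaled to keep the physical window at ≈ 88 µm (the
scale-consistency test verifies FV metrics move by well under a percentage
point between 256 and 512 px); and statistical calibration over hundreds
of replicate cohorts (type-I error of the screen) uses the generator's
record-level fast path, because those properties belong to the statistics
stage, not to the image stage. The acceptance script runs the full
image-resolution cohort end to end.

## Known limitations

* The compensation model assumes shadowing is multiplicative and shared
  between channels; real attenuation is depth- and wavelength-dependent.
* ΔFV inherits the binarization's sensitivity to the window radius; values
  are comparable only at a fixed physical window size.
* The generator's growth model is isotropic; directional growth analysis
  is out of scope.
* GEE standard errors use the standard sandwich without small-sample
  correction; with 23 clusters they are adequate but not exact.
* The ICC helpers assume exactly two graders with complete data.
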