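---
title: "Quantifying radial and polar nuclear organization in 3D: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying radial and polar nuclear organization in 3D: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucradial)
```

nucradial measures how fluorescent signals — FISH-labelled pericentromeric
satellite repeats, immunostained heterochromatin marks — are organized
inside early-embryo nuclei imaged as anisotropic confocal z-stacks. This
vignette explains the models and procedures, the parameters that matter,
the design choices that were genuinely open, and what the synthetic
phantom validation does and does not establish about real data.

## The imaging model

A stack is a 3D scalar grid with physical voxel spacing $(s_x, s_y, s_z)$
in micrometers. Confocal voxels are strongly anisotropic (a typical
acquisition uses ~0.1–0.25 µm in-plane with a 0.37 µm z-step), so every
geometric operation in the package — distance transforms, structuring
elements, Gaussian sigmas, watershed priorities, gap distances — works in
physical units, never voxel counts. Compiled kernels (Rcpp) provide the
3D primitives R lacks: exact anisotropic Euclidean distance transforms
(separable lower-envelope algorithm), 6-connected component labelling,
flat grayscale morphology, morphological reconstruction (hybrid
raster/queue algorithm), and seeded watershed by priority flooding with
raster-order tie-breaking, which makes every segmentation bit-reproducible.

## Radial position: EVF and d_max

The eroded volume fraction (EVF) of a point is the fraction of nuclear
volume lying between the point and the nuclear surface: 0 at the
periphery, 1 at the center. Its defining virtue is shape universality:
for *any* nucleus shape, uniformly distributed points have uniformly
distributed EVF, so departures from uniformity are attributable to the
signal, not the geometry.

On a digital mask the EVF is computed by ranking the
distance-to-background of all $N$ mask voxels. Digital masks carry heavy
tie multiplicities — the entire one-voxel boundary shell of a sphere
shares one distance value, easily 15–20 % of a small mask — and the tie
convention decides whether the uniformity property survives
discretization:

* **graded** (default): ties are broken deterministically in voxel scan
  order, every voxel gets a distinct rank, and EVF values form the exact
  uniform grid $(k - \tfrac12)/N$. The uniform-points property then holds
  *exactly* on the discrete mask. Within a tie shell the ordering is
  arbitrary, which is harmless: all voxels of the shell are radially
  equivalent by construction.
* **mid**, **strict**, **inclusive**: classical mid-rank and one-sided
  conventions, available for comparison. Mid-rank is unbiased in
  expectation but places atoms of probability on tie shells, which
  visibly distorts Kolmogorov–Smirnov checks against $U(0,1)$ on
  symmetric masks.

The nucleus is then split into $F$ fractions of equal voxel count
(default $F = 1000$, clamped to $N$ for small masks), ordered periphery →
center, so the mean EVF per fraction rises linearly. For a signal —
either raw voxel intensities inside the mask (*intensity* mode, the
default) or binary spot-mask voxels (*spots* mode) — the per-fraction
share $p_k$ and cumulative $C_k$ give

$$ d_{\max} = C_{k^*} - k^*/F, \qquad k^* = \arg\max_k |C_k - k/F|, $$

a signed statistic in $[-1, 1]$: positive = peripheral bias, negative =
central bias. "Largest signed difference" could also be read as
$\max_k (C_k - k/F)$; both are implemented (`convention` argument), the
magnitude-with-sign reading is the default because it preserves the
advertised symmetry between peripheral and central biases. Ties in $k^*$
take the smallest (most peripheral) fraction. Intensity mode uses the raw
in-mask intensities without background subtraction; a uniform background
therefore dilutes $|d_{\max}|$ toward 0 but cannot flip its sign — worth
remembering when comparing magnitudes across channels with different
background levels.

## Polarity: centroid distance with a simulated null

Are the spots confined to one sector of the nucleus? The statistic is the
distance between the nuclear centroid and the unweighted mean of the spot
centroids. Raw distances confound polarity with nuclear size and shape,
so the mask is first shape-normalized: translate to the centroid, whiten
the second-moment matrix of the voxel coordinates with the overall scale
fixed so the transform preserves volume ($\det W = 1$), and divide
distances by the radius of the volume-equivalent ball. For a sphere of
radius $R$ the transform is the identity about the center with
normalization radius $R$; distances land in $[0, 1]$ with 1 at the
boundary scale (values beyond 1, possible for extreme shapes, are clamped
and flagged).

The null distribution is simulated: 500 patterns of $n$ points drawn
independently and uniformly over the mask voxels (point sampling, not
spot-sized patterns — a deliberate simplification recorded here as a
limitation; for ~0.4 µm spots in a ~10 µm nucleus the difference is
negligible). The p value compares the observed distance $d$ with the null
sample via

$$ t = \frac{\overline{d_{\text{null}}} - d}{\mathrm{sd}(d_{\text{null}})},
   \qquad p = P(T_{n_{\text{sim}}-1} \le t). $$

The scaling by the null *standard deviation* — not the standard error of
the null mean — is the load-bearing choice: under spatial randomness the
observed distance is one draw from the null population, so this statistic
is approximately pivotal and p is near-uniform on $[0,1]$, which is what
makes "a uniform p distribution indicates random spot placement" true and
gives the test its nominal size (measured type-I error 0.05 at
$\alpha = 0.05$ over 200 null phantoms). Scaling by the standard error
(`method = "sem"`) yields a test of "is the null mean exactly $d$", which
rejects almost half of all truly random patterns at $\alpha = 0.05$ and
is provided only for comparison. An empirical-quantile p
(`method = "empirical"`) is the distribution-free alternative; its
resolution is limited to $1/(n_{\text{sim}}+1)$, which is why the
t-approximation is the default. The null is mildly right-skewed
(chi-like), so the t-based p is approximate in the extreme upper tail;
p values near 1 saturate around 0.99 rather than 0.999.

## Segmentation

**Nuclei.** The DNA channel is smoothed with any ordered combination of
median, Gaussian, opening, closing, and gray hole filling; the pipeline
default is `median(1)` + `gray_hole_fill`. Hole filling (reconstruction
by erosion from a border marker) matters specifically because NPBs are
*dark* voids: without it they punch holes through the nuclear mask at
thresholding, and with it the voids are preserved in the raw channel for
NPB detection while the mask stays solid. Three classical thresholds are
available on 256-bin histograms: Otsu (between-class variance), maximum
entropy (Kapur), and RATS ($t = \sum w I / \sum w$ with $w$ the squared
gradient magnitude — robust for sharp-edged bright objects). Foreground
is intensity ≥ threshold. Components smaller than `min_volume` (default
200 µm³, set lower for phantom-scale nuclei) or with more than
`max_border_fraction` (default 0.3) of their surface voxels on the image
border are discarded. Touching nuclei are split by watershed on the
negated anisotropic distance map, seeded at regional maxima after
h-maxima suppression (`h` in µm; maxima shallower than `h` do not seed an
object). The split preserves the voxel set and is idempotent.

**Spots.** Denoising is a physical-units Gaussian ($\sigma$ default
0.15 µm) followed by a white tophat (radius default 1 µm) — a high-pass
stage that removes smooth background while preserving compact bright
structures, and makes the subsequent threshold exactly invariant to
additive background offsets. Spot voxels are mask voxels whose denoised
signal reaches a quarter of the in-mask maximum. The quarter-maximum is
taken on the *denoised* signal (the procedure is ambiguous between raw
and denoised; denoised is the noise-robust reading and the one
implemented). Components below `min_spot_volume` (default 0.05 µm³) are
dropped; centroids are intensity-weighted by default (geometric optional).

**NPBs.** The counting procedure for dark bodies is a reconstruction —
real studies often score them visually — and is labelled as such:
intensity is inverted inside the nuclear mask, smoothed with a
*normalized masked* Gaussian (outside voxels carry zero weight, so the
mask boundary cannot bleed into the histogram), thresholded by Otsu on
the in-mask histogram, and filtered by volume (≥ 1 µm³) and sphericity
(≥ 0.6), with $\text{sphericity} = \pi^{1/3}(6V)^{2/3}/A$. The surface
area $A$ is estimated from exposed voxel faces scaled by the asymptotic
$2/3$ staircase correction, which is unbiased for smooth surfaces in
general position but *underestimates* the area of thin axis-aligned
slabs — elongated structures should be oriented off-axis in validation
fixtures. A guard rejects detections in which the dark phase covers more
than half the nucleus (an Otsu failure mode on void-free noisy images,
not a plausible NPB configuration). Association: an NPB is associated
with a channel when at least one spot voxel lies within `gap` (default
0.5 µm) of it, distances measured voxel-center to voxel-center by
anisotropic distance transform; association counts are monotone in the
gap by construction.

## The phantom generator

The generator emulates the study conditions so that every downstream
stage is testable with known ground truth:

* **Geometry**: a deformed ellipsoid — the base ellipsoid boundary
  displaced radially by a smooth random quadratic-form direction field
  scaled by `deform_amplitude` ∈ [0, 0.3], hence star-shaped and
  connected. Default grid 128×128×48 at (0.14, 0.14, 0.37) µm with
  semiaxes (7.2, 6.5, 6.0) µm, i.e. a ~1180 µm³ nucleus: within the
  observed 2-cell → 16-cell range (~1150–2800 µm³) while leaving a
  deformation margin inside the grid. The z-step is the acquisition
  value; the xy pixel size and detector noise are not reported for the
  source imagery and are configurable assumptions.
* **Spots**: 24 (channel A) and 12 (channel B) — the metaphase
  expectations for the two satellite families. The radial law is exact by
  construction: a target EVF $u \sim \mathrm{Beta}(a, b)$ is drawn per
  spot and the spot is placed at the candidate voxel of nearest EVF rank,
  so the generated bias is expressed in the same EVF definition the
  analysis uses. $(1,1)$ is uniform; $(5,1)$ center-loaded; $(1,5)$
  peripheral. Polarity is imposed by rejection with weight
  $e^{\lambda \cos\theta}$ toward a pole; $\lambda = 0$ is the null.
  Centers keep a minimum separation (default $3 \times$ spot radius) so
  rendered spots remain resolvable objects, as chromocenters are; set it
  to 0 for pure point-process sampling (the samplers' uniformity tests do).
* **NPBs**: non-overlapping dark spheres with two-voxel clearance,
  rendered at a dimming factor (< 1) of the nucleoplasm level. Spot
  centers are excluded from NPB neighborhoods so the ground-truth masks
  stay disjoint.
* **Rendering and noise**: spots are isotropic Gaussian blobs scaled so
  the quarter-maximum radius equals the nominal spot radius (making the
  quarter-max segmentation rule analytically checkable); optional Poisson
  shot noise then Gaussian read noise; 8-bit clipping and quantization.
  Every output is a pure function of (spec, seed).

What phantom validation does **not** establish: robustness to uneven
illumination and chromatic aberration, to textured chromatin background
(real nucleoplasm is not flat), to true PSF anisotropy (blobs are
isotropic Gaussians, not Airy patterns), to touching *signals* between
neighboring nuclei, or to the doublet overcounting expected after
replication. Those caveats bound what the green test suite says about
real images.

## Numerical choices and degenerate inputs

Problem sizes in the tests and drivers: the suite and the acceptance
script run on 64×64×28 phantom grids at (0.2, 0.2, 0.37) µm — ~18k-voxel
nuclei — with 100-phantom radial batches, 200-nucleus polarity
calibration at 500 simulated patterns each, and 50-phantom segmentation
recovery at SNR 10; the demonstration cohort is 5 stages × 4 nuclei.
These sizes were chosen so a full run completes in minutes on one core
while keeping every estimate's Monte-Carlo error well inside the bands it
is tested against.

Other choices worth recording: histogram thresholds use native 8-bit bins
when the data are integral in [0, 255], otherwise 256 equal bins over the
range; constant images raise a "degenerate histogram" error rather than
returning an arbitrary cut. `equal_volume_fractions` warns and clamps
when $F$ exceeds the voxel count. Empty spot sets propagate as zeros
through `spot_metrics` and as NA-flagged fields through
`measure_nucleus`; the polarity test refuses empty spot sets and
zero-variance nulls. Watershed ties, EVF rank ties, and fraction
boundaries all resolve in deterministic raster order, so every result is
reproducible bit-for-bit from (config, seed). Distance maps treat
out-of-grid space as foreground-free only through in-grid background;
masks are expected not to touch the grid border (the border filter in
nucleus segmentation enforces this upstream).

Statistical layer defaults: spot-count tests against theoretical
metaphase counts are two-sided (recomputing the published 2-cell
summaries — n = 24, 26.17 ± 5.08 vs 24 and 16.96 ± 6.10 vs 12 —
reproduces the printed p values 0.04788 and 0.00059 only under the
two-sided reading, which fixes the convention). Binary annotation
frequencies use Fisher's exact test (chi-square with continuity
correction optional). No multiple-testing correction is applied by
default, matching the source analysis; a Benjamini–Hochberg adjustment
can be applied to any p-value column with `p.adjust` if desired.

## Known limitations

* The NPB detector is an automated stand-in for what may have been visual
  counting; its absolute counts should not be compared against published
  NPB counts without calibration.
* The sphericity estimator's staircase correction assumes generic surface
  orientation; axis-aligned thin structures score too high.
* The t-approximate polarity p is conservative in the deep upper tail
  (p ≈ 1 region); use `method = "empirical"` when exact uniformity of
  that region matters.
* Intensity-mode d_max is background-diluted; spots-mode d_max on
  segmented signals is the sharper statistic when segmentation is
  trustworthy.
* One nucleus per phantom; multi-nucleus fields are validated only via
  tiling in the segmentation tests.
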