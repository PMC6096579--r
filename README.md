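# nucradial

Quantitative 3D analysis of nuclear organization in early-embryo confocal
stacks: where do pericentromeric heterochromatin signals sit inside the
nucleus, are they polarized, and how do they relate to nucleolar precursor
bodies (NPBs)?

The package is written for microscopists and embryologists who image
DNA-counterstained nuclei plus one or two FISH/immuno channels as
anisotropic z-stacks (e.g. 8-bit frames with a 0.37 µm z-step) and want a
reproducible, testable pipeline from raw voxels to stage-wise statistics.
Because such datasets are rarely public, the package ships a synthetic
phantom generator with exact ground truth; every stage of the pipeline is
validated against it.

## What it computes

**Radial position — EVF and d_max.** The eroded volume fraction of a point
x in a nucleus is the fraction of nuclear volume lying between x and the
nuclear surface: EVF = 0 at the periphery, 1 at the center, and EVF of
uniformly distributed points is uniform on [0, 1] *for any nuclear shape*.
The nucleus is divided into F = 1000 fractions of equal volume ordered
periphery → center; with p_k the share of channel signal in fraction k and
C_k = Σ_{j≤k} p_j, the radial statistic is the signed deviation of largest
magnitude from the uniform diagonal,

    d_max = C_k* − k*/F,   k* = argmax_k |C_k − k/F|,

so d_max ∈ [−1, 1], positive = peripheral bias, negative = central bias.

**Polarity.** After moment-based shape normalization (centroid translation
+ volume-preserving whitening of the second-moment matrix), the distance
between the nuclear centroid and the centroid of all spots is expressed in
units of the volume-equivalent ball radius (range 0–1). It is compared
with 500 simulated uniform spot patterns per nucleus; the one-sided p value
is uniform under spatial randomness, small when spots are polarized, near 1
when they are centrally balanced.

**Segmentation.** Nuclei: median/Gaussian/opening/closing/gray-hole-fill
preprocessing, Otsu / maximum-entropy / RATS thresholds, size and
border-truncation filters, watershed on the anisotropic distance map for
touching nuclei. Spots: Gaussian + white tophat denoising, then the
quarter-maximum rule (voxels ≥ 1/4 of the in-nucleus maximum). NPBs: dark
round bodies found by inverted-contrast Otsu with volume and sphericity
filters, then scored for association with spot signals within a 0.5 µm gap.

**Statistics.** One-sample t tests of spot counts against the metaphase
expectations (µ0 = 24 and 12 for the two satellite families),
Kolmogorov–Smirnov comparisons of d_max between stages, linear models with
a stage factor and a covariate (with Shapiro–Wilk and Bartlett
diagnostics), and Fisher tests for binary annotation frequencies.

## Worked example

```r
library(nucradial)

spec <- phantom_spec(grid_shape = c(64, 64, 28), spacing = c(0.2, 0.2, 0.37),
                     nucleus_semiaxes = c(4.8, 4.2, 3.8),
                     deform_amplitude = 0.1, radial_bias = c(3, 1),
                     n_npb = 2, npb_radius = 0.8,
                     noise = list(gaussian_sd = 16, poisson_gain = 0),
                     seed = 11)
ph  <- simulate_phantom(spec)
res <- analyze_nucleus(ph$channels, stage = "2-cell", seed = 42)
res$record[, c("nuclear_volume", "n_spots_a", "n_spots_b",
               "d_max_a", "polarity_p_a", "n_npb")]
```

```
  nuclear_volume n_spots_a n_spots_b    d_max_a polarity_p_a n_npb
1       301.2096        23        12 -0.0536431    0.9509047     2
```

Reading: the segmented nucleus measures 301.21 µm³ against a ground-truth
301.24 µm³; 23 of the 24 + 12 generated spots are recovered at SNR 10
(two close spots merge under the quarter-maximum rule); d_max is negative
because the generator placed spots with a center-loaded Beta(3, 1) radial
law — the intensity-mode statistic includes the uniform in-nucleus
background, which dilutes its magnitude but not its sign; the polarity p
of 0.95 says the spot centroid sits closer to the nuclear centroid than a
typical random pattern — no polarity, mild central balance; both NPB
voids are detected.

The `analysis/` scripts run the same chain as a narrative workflow — a
5-stage, 20-nucleus cohort with shrinking nuclei and a transient
peripheral shift of the radial law:

```sh
Rscript analysis/01_simulate.R   # writes TIFF stacks + ground truth
Rscript analysis/02_analyze.R    # segments and measures every nucleus
Rscript analysis/03_stats.R      # stage tables, KS tests, linear model
```

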