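---
title: "Methods: polarimetric SHG tumor-margin mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polarimetric SHG tumor-margin mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pshgmargin)
```

This vignette explains the models and procedures implemented in
`pshgmargin`, the assumptions behind them, the tunable parameters and
their defaults, what the synthetic phantom does and does not emulate, and
the numerical and design choices made where the problem left them open.

## The measurement model

Widefield P-SHG acquires 16 images per field of view: the SHG intensity
for every combination of four incoming and four analyzed polarization
states (left/right circular, vertical/horizontal linear). For each
incoming state the analyzed intensities combine into Stokes elements

* `s0 = I_HLP + I_VLP` (total SHG intensity),
* `s1 = I_HLP − I_VLP` (linear polarization difference),
* `s3 = I_RCP − I_LCP` (circular polarization difference),

and the five per-pixel polarimetric parameters are `I_CP`, the R-ratio
`R = 1 + 2A + 2√(A² − 1)` with `A = (s0^RCP + s0^LCP)/(s3^RCP − s3^LCP)`,
`DCP`, `SHG-CD` and `SHG-LD` (formulas in the function documentation).
Assumptions worth making explicit:

* **No extra Stokes normalization.** The elements are used in
  exposure-consistent camera counts. Every downstream parameter is either
  a ratio of Stokes elements or enters the analysis only after
  feature standardization, so a global intensity scale cancels. This is a
  documented convention of this package, not a physical claim.
* **`s1` is computed but unused.** None of the five parameters
  constrains it; it is retained for completeness and the phantom sets it
  to zero.
* **Per-pixel invalidity is not fatal.** `R` is undefined where
  `|A| < 1` (negative radicand, a noise artifact) or `|A| > 1e6`
  (near-zero denominator; the cap marks numerically meaningless pixels);
  `DCP > 1.05` is unphysical and invalidated, values in `(1, 1.05]` are
  clamped to 1. Invalid pixels carry `NA` and are excluded from all
  tile statistics.

## SNR calibration and thresholding

Repeated frames give a per-pixel mean `μ` and standard deviation `σ`;
`SNR = μ/σ` against `μ` is fitted with a power law on log–log axes. For
shot-limited noise the exponent is 0.5. Two practical points:

* **Censoring at the detector floor.** Counts cannot go below zero, so
  pixels whose noise amplitude is comparable to their mean have a
  flattened, censored `μ/σ` relation; a naive one-pass fit over all
  pixels is biased (we observe `b ≈ 0.26` instead of `0.5` on shot-noise
  phantoms). `fit_snr_calibration()` therefore refits over pixels whose
  initially predicted SNR is at least 2, where censoring is negligible;
  on shot-noise phantoms with gain 0.05 this recovers `a = 0.24`
  (theory: `√gain = 0.224`) and `b = 0.50`.
* **Thresholding is extrapolation by design.** The mask keeps a pixel
  iff the predicted SNR at its `I_CP` is ≥ 1 (inclusive boundary). Dim
  pixels lie below the refit domain; predicting their SNR from the
  calibrated law is the intended use, and only above-domain inputs
  trigger an extrapolation warning.

In the full pipeline the calibration is fitted on a repeated-frame stack
of a 256×256 window straddling the boundary (8 frames by default) and
applied to the single-frame analysis stack, mirroring how a microscope
calibration is measured once and reused.

## Tiling, GLCM texture and the 36-feature table

Parameter maps are tiled into 128×128-pixel sub-images (no partial
tiles). Per tile and parameter, texture comes from a grey-level
co-occurrence matrix at displacement 1 for angles 0°, 45°, 90°, 135°,
counted symmetrically (both orders), averaged over angles and normalized.
Key choices:

* **Grey levels.** `N_g = 64` by default: fine enough to resolve
  continuous parameters, dense enough for 128² tiles. The quantization
  range is global per parameter — robust 1st–99th percentiles over all
  valid pixels of the mosaic — so texture is comparable across tiles,
  which inter-tile clustering requires. Features are invariant to adding
  a constant to a map when the range shifts with it.
* **Background pairs.** Any pixel pair with at least one invalid member
  is dropped entirely; a tile with no valid pair yields sentinel (`NA`)
  features and is excluded from clustering.
* **Correlation sign.** The correlation feature is implemented so that a
  perfectly positively correlated tile scores +1 and a perfectly
  negatively correlated one −1, the limits the method's description
  states; a printed variant of the formula carries a leading minus sign
  incompatible with those limits and is treated as a typographical slip.
* **Summary statistics.** MAD is the mean absolute deviation about the
  *mean* (chosen over the median for consistency with the name). Pixel
  density is the fraction of SNR-valid pixels in the tile. Tiles with
  density < 0.1 (configurable) or with a majority of pixels inside the
  exclusion mask (adipose/vessel stand-ins) are dropped.

The table has exactly 36 feature columns: pixel density plus
{mean, MAD, contrast, correlation, entropy, ASM, IDM} for each of the
five parameters.

## PCA, subsets, clustering and the margin statistic

Features are standardized to z-scores (zero-variance columns are an
error; rows with sentinel features are dropped and logged). PCA is the
eigendecomposition of the resulting correlation matrix; eigenvalues sum
to the feature count, and the Kaiser criterion retains components with
eigenvalue ≥ 1 — the boundary is inclusive, since a component carrying
exactly one feature's worth of variance is not "less than" the original
parameters. Component signs are fixed deterministically (largest-|loading|
positive) so maps and transferred projections are reproducible.

Eight data subsets are clustered: `INT` = {intensity mean, MAD, pixel
density}; `INT+TXT` = INT plus the intensity texture features; `POL` =
{mean, MAD} of all five parameters plus pixel density; `ALL` = all 36;
`PC1`–`PC4` = single score columns. The membership of `INT` and `POL` is
interpretive (the verbal subset descriptions are ambiguous between
mean-only and mean+MAD); mean+MAD was chosen. Non-PC subsets are
standardized before K-Means, consistent with the PCA standardization; PC
scores are used as-is.

K-Means uses the squared-Euclidean objective with 50 seeded restarts —
stable at these problem sizes (10²–10³ rows, 1–36 columns). Cluster
indices are arbitrary, so labels are canonicalized: cluster 1 is the
cluster with higher mean pixel density (the normal-like side), which the
continuous map, occupancies and IIOD all depend on. Silhouette scores use
Euclidean distance; a singleton cluster's point scores 0 (standard
convention avoiding an undefined division). Binary label `B` and
silhouette `S` fuse into `C = B + (1 − S)/2` (B = 1) or `B − (1 − S)/2`
(B = 2): a bijection per branch onto [1, 2] with the no-association
boundary at 1.5, which moves negative-silhouette points to the opposite
side. Maps of `C` are median-filtered with a 3×3 window that uses only
present values — missing (rejected) cells stay missing, borders use
shrunken neighborhoods, and no padding values are invented.

Against a ground-truth partition (tiles labelled by pixel majority; exact
ties are excluded rather than assigned), occupancies weight each tile by
`|C − 1.5|`, with effective membership by the side of 1.5 rather than the
raw K-Means label — this is what lets wrongly-labelled, negative-silhouette
tiles count toward the cluster they behave like. `Q_{1,r} + Q_{2,r} = 1`
wherever a region carries weight; IIOD multiplies the four absolute
occupancy differences and is invariant to swapping cluster indices
together with sides. The subset with maximal IIOD wins (ties resolve to
the first listed). The boundary estimate is the 1.5-crossing of the
median-filtered map's per-column mean, interpolated between column
centers; with several crossings the steepest is taken.

When comparing subsets by silhouette, the harmonic mean of the two
per-cluster means is reported alongside the arithmetic mean: it weights
the weaker cluster more heavily, deflating subsets that dump almost all
tiles into one cluster. It is undefined (reported `NA`) when a cluster's
mean silhouette is non-positive. Note that silhouette comparisons across
subsets of very different dimensionality are confounded — unstructured
3-D data clusters with silhouette ≈ 0.25 while a genuine 36-D split may
score lower — which is why the 1-D PC subsets tend to carry the largest
harmonic means, and why margin detection relies on IIOD, not on
silhouette alone.

PC transfer to a new region standardizes the new table with its own
column statistics by default (`standardize = "reference"` reuses the
stored ones; which variant the original analysis used is not knowable, so
both are supported) and projects onto the stored loading vector; label
canonicalization makes the result invariant to the loading's sign.

## The synthetic phantom

The phantom emulates a margin-imaging geometry: a mosaic with a tumor-like left
and normal-like right side separated at a known pixel column (default: a
single 1024×1024 field, midline boundary, 128-pixel tiles). Defaults
follow the contrasts reported in the P-SHG tumor-imaging literature where
available and field-plausible values where not:

* tumor side: fiber density 0.35, mean `I_CP` 300 counts — lower than
  the normal side's 0.65 / 800 counts, reproducing the well-documented
  drop in SHG intensity and bright-pixel density in tumor ECM;
* orientation disorder: SHG-CD/LD are smoothed Gaussian random fields
  with per-region correlation length (3 px tumor vs 14 px normal,
  spread 0.55). Short correlation lengths produce the
  contrast/entropy/IDM texture heterogeneity that the dichroism-sensitive
  components key on, without a full χ⁽²⁾ tensor model;
* R-ratio and DCP: tumor 4.4 ± 0.5 / 0.35 ± 0.10, normal 3.7 ± 0.4 /
  0.30 ± 0.08. Tumor-vs-normal differences in R-ratio and DCP are not
  quantitatively characterized in the literature, so these are free
  parameters chosen once as plausible — not tissue-calibrated;
* noise: shot-like with variance `mean/gain` (default gain 0.05, i.e.
  SNR ≈ `√(0.05 μ)` ≈ 3.9–6.3 on fiber pixels, well below 1 on the
  2-count background), clamped at zero counts.

Feasibility is handled exactly rather than by clipping the forward
model: the Stokes inversion requires `|s3| ≤ s0`, and the R-formula's
positive branch maps `A ≥ 1` to `R ≥ 3`, so R is sampled truncated to
`[3.05, 25]` and DCP by inverse-CDF truncated-normal sampling on the
exact per-pixel interval compatible with the sampled `I_CP`, `R` and
SHG-CD (a closed-form interval; no retry loop needed). Dichroism fields
are clipped to [−1.9, 1.9] with the clip count recorded. The recorded
truth maps are the *realized* values, which is what makes the zero-noise
roundtrip exact to machine precision.

What the phantom does **not** emulate: real fiber morphology (fibers are
i.i.d. bright pixels, not connected structures), the physical
χ⁽²⁾-tensor dependence of the parameters on fiber orientation, the
empirical covariance between parameters in tissue, H&E appearance, and
instrument artifacts (retarder imperfections, uneven illumination).
Passing tests therefore demonstrate that the analysis chain is correct
and sensitive to the encoded contrasts — not that it will perform
identically on patient tissue.

## Problem sizes and determinism

The shipped tests exercise 256×256 fields with 32-pixel tiles for module
checks and 1024×1024 mosaics with 128-pixel tiles (64 sub-images) for the
end-to-end margin-recovery suite (10 seeds), with the SNR calibration
fitted on 256×256 windows at 8 frames — sizes chosen so the whole suite
runs in minutes on one CPU while keeping every stage's statistics
non-degenerate. One master seed drives every stochastic stage through
fixed offsets (phantom, stack synthesis, calibration frames, K-Means), so
stages rerun in isolation reproduce the full run, and identical
configurations produce byte-identical tabular outputs.

## Known limitations

* The chiral C-ratio (χ⁽²⁾xyz/χ⁽²⁾zxx) is not computed.
* Only binary K-Means is provided; no k > 2, hierarchical or model-based
  alternatives, and no spatial regularization beyond the median filter.
* The margin is a single vertical divide in the scored geometry;
  arbitrarily shaped boundaries are supported through label rasters for
  occupancy/IIOD, but the profile-crossing boundary estimator assumes a
  predominantly left/right transition.
* Silhouette-based subset ranking inherits the dimensionality confound
  described above; IIOD is the margin-detection statistic.
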