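# pshgmargin

Unsupervised tumor-margin mapping from widefield polarimetric
second-harmonic generation (P-SHG) imaging of extracellular-matrix
collagen.

Collagen in the extracellular matrix (ECM) is noncentrosymmetric and
generates strong second-harmonic signal; tumors disorganize and degrade
that collagen. `pshgmargin` implements a complete, unsupervised pipeline
that turns a 16-state polarization-resolved SHG image stack (4 incoming x
4 analyzed polarization states: LCP, RCP, VLP, HLP) into a spatial map of
normal-like vs tumor-like tissue and a localized margin — using ECM
features only, no cellular information. It is aimed at researchers in
nonlinear optical microscopy and computational pathology who want a
testable, scriptable reference implementation of this analysis chain.

## The method

1. **Stokes–Mueller polarimetry.** Per incoming state, `s0 = I_HLP +
   I_VLP`, `s1 = I_HLP − I_VLP`, `s3 = I_RCP − I_LCP` from the analyzed
   intensities; frames are averaged first. Five per-pixel parameters
   follow:
   * `I_CP = (s0^RCP + s0^LCP)/2` — circularly polarized SHG intensity;
   * `R = 1 + 2A + 2√(A² − 1)` with `A = (s0^RCP + s0^LCP)/(s3^RCP −
     s3^LCP)` — the achiral susceptibility ratio χ⁽²⁾zzz/χ⁽²⁾zxx;
   * `DCP = (|s3^RCP|/s0^RCP + |s3^LCP|/s0^LCP)/2` — degree of circular
     polarization;
   * `SHG-CD = 2(s0^RCP − s0^LCP)/(s0^RCP + s0^LCP)` and
     `SHG-LD = 2(s0^VLP − s0^HLP)/(s0^VLP + s0^HLP)` — circular and
     linear dichroism, sensitive to out-of-plane and in-plane fiber
     orientation.
   A per-pixel SNR calibration (`SNR = a·μ^b`, fitted from repeated
   frames) thresholds the maps at SNR ≥ 1.
2. **Texture featurization.** The mosaic is tiled into 128×128
   sub-images. Per tile and parameter: mean, mean absolute deviation,
   and five Haralick features (contrast, correlation, entropy, ASM, IDM)
   from a symmetric, background-excluding, angle-averaged grey-level
   co-occurrence matrix (d = 1; 0°, 45°, 90°, 135°), plus the tile's
   pixel density — 36 features per sub-image.
3. **PCA** on the standardized feature table, with the Kaiser criterion
   (eigenvalue ≥ 1) marking the informative components.
4. **Binary K-Means + silhouette.** For eight data subsets (INT,
   INT+TXT, POL, ALL, PC1–PC4), k = 2 K-Means labels `B` are fused with
   silhouette scores `S` into a continuous association
   `C = B ± (1 − S)/2 ∈ [1, 2]` (1.5 = no association), mapped onto the
   grid, median-filtered (NA-preserving), and averaged per column.
5. **Margin scoring.** Against a ground-truth left/right partition,
   silhouette-weighted occupancies
   `Q_{a,r} = Σ_{i∈a,r}|C_i − 1.5| / Σ_{j∈r}|C_j − 1.5|` feed the
   inter/intra-cluster occupancy difference
   `IIOD = |Q_{1,L} − Q_{2,L}|·|Q_{1,R} − Q_{2,R}|·|Q_{1,L} − Q_{1,R}|·|Q_{2,L} − Q_{2,R}| ∈ [0, 1]`;
   the subset with maximal IIOD localizes the margin via the 1.5-crossing
   of its vertical profile. A stored PC loading vector can be transferred
   to new regions (`transfer_pc_projection()`).

Because raw patient stacks are not distributable, the package ships a
first-class synthetic phantom generator (`phantom_config()`,
`generate_phantom()`, `synthesize_stack()`) that inverts the parameter
definitions into Stokes elements and 16 raw images, with a known
tumor/normal boundary, configurable region contrasts, orientation-disorder
texture and shot-like noise. Zero-noise phantoms roundtrip all five
parameter maps to machine precision, so every downstream stage is testable
end to end.

## Worked example

```r
library(pshgmargin)

cfg <- pipeline_config(phantom = phantom_config(seed = 42), seed = 42)
res <- analyze_phantom(cfg)   # phantom -> Stokes -> maps -> features ->
                              # PCA -> clustering -> margin

glance(res$calibration)
#>           a         b n_pixels sigma_resid   mu_min   mu_max
#> 1 0.2393622 0.5015334    90060   0.2908344 35.75352 3388.085

glance(res$pca)
#>   n_features n_obs n_retained cum_var_retained
#> 1         36    64          4        0.8945074

res$margin
#>    subset  q1_tumor  q2_tumor q1_normal q2_normal        iiod  best
#> 1     INT 0.0000000 1.0000000 1.0000000 0.0000000 1.000000000  TRUE
#> 2 INT+TXT 0.0000000 1.0000000 1.0000000 0.0000000 1.000000000 FALSE
#> ...

res$boundary[res$boundary$subset == "INT", ]
#>   subset boundary_tiles boundary_px
#> 1    INT       4.000251    512.0321
```

The shot-noise calibration recovers the square-root law (`b ≈ 0.50`);
four PCs pass the Kaiser criterion; the best subset separates the two
sides perfectly (each cluster confined to one side gives the IIOD maximum
of 1) and the estimated boundary (tile column 4.00, pixel 512) sits on
the phantom's true midline divide at pixel 512. `plot_cluster_map()`,
`plot_vertical_profile()` and `autoplot()` render the cluster maps,
profiles and scree plot; `run_pipeline()` additionally writes TIFF maps,
CSV tables and a JSON manifest.

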