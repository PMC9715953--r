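Package: pshgmargin
Title: Unsupervised Tumor-Margin Mapping from Widefield Polarimetric SHG Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps extracellular-matrix collagen ultrastructure from widefield
    polarization-resolved second-harmonic generation (P-SHG) image stacks and
    localizes a tumor margin without supervision. Provides Stokes-element
    computation and the five polarimetric parameter maps (circularly polarized
    SHG intensity, R-ratio, degree of circular polarization, SHG circular and
    linear dichroism), SNR calibration and thresholding, grey-level
    co-occurrence (GLCM) Haralick texture features over sub-image tiles with
    background exclusion, PCA with the Kaiser criterion, binary K-Means
    clustering fused with silhouette scores into a continuous cluster map,
    and an inter/intra-cluster occupancy difference (IIOD) statistic scored
    against a ground-truth boundary. A synthetic phantom generator with a
    known margin makes the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
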