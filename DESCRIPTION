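Package: nucleoquant
Title: Quantitative Phenotyping of Nucleolar Condensates from Fluorescence Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Image quantification toolkit for classifying membrane-less
    nuclear bodies as polymer-polymer versus liquid-liquid phase-separated
    condensates from cropped 3D fluorescence microscopy stacks. Implements
    Otsu background thresholding of z-stacks and projections, gray-level
    co-occurrence texture homogeneity of sum-intensity projections,
    per-signal volume / mean-intensity-above-background / compression
    morphometry with robust outlier gating and volume-intensity correlation,
    photobleach-corrected FRAP recovery curves with percent recovery,
    two-channel voxelwise Pearson correlation and relative positional
    variance, group statistics (rank-sum, ANOVA + Tukey HSD), batch
    orchestration over TIFF manifests, and a ground-truthed synthetic
    3D-image generator covering both condensate regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
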