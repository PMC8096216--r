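# nucleoquant

Quantitative phenotyping of nucleolar condensates from cropped 3D
fluorescence microscopy stacks.

Membrane-less nuclear bodies can assemble in two mechanistically distinct
ways. A **liquid–liquid phase-separated (LLPS)** condensate behaves like a
droplet: adding material grows its volume while its internal concentration
stays fixed. A **polymer–polymer phase-separated (PPPS)** condensate — e.g.
a crosslinked chromatin domain such as the budding-yeast rDNA array — is
*compressible*: it conserves material, so compaction shrinks its volume and
raises its concentration. `nucleoquant` implements the image statistics
that discriminate the two regimes from single-signal crops (the 55 × 55
pixel / 3.5 × 3.5 µm convention) of z-stacks, for cell-biology labs
quantifying condensate behavior in vivo:

- **Background segmentation** — per-stack single-level Otsu threshold
  (foreground = intensities strictly above *t*); sub-threshold voxels are
  excluded from all downstream statistics.
- **Texture homogeneity** — from the sum-intensity projection, after
  min–max rescaling and quantization to 8 gray levels, the gray-level
  co-occurrence matrix *P(i, j)* over horizontally adjacent valid pixels is
  scored as
  *H* = Σᵢⱼ *p(i, j)* / (1 + |i − j|), with *p = P / n_pairs* ∈ (0, 1].
  Flat droplets score high; sharp puncta score low.
- **Morphometry** — volume *V* (voxels above background), mean intensity
  above background *Ī* = (Σ foreground)/V − *t* (a concentration proxy),
  compression *Ī/V*, heterogeneity (population SD of the foreground after
  min–max rescaling), plus robust (3 × scaled-MAD) outlier gating over six
  measures and the population Pearson correlation r(V, Ī): ≈ 0 for LLPS,
  strongly negative for PPPS.
- **FRAP** — photobleach-corrected, normalized recovery curves from
  (pre-bleach, laser-spot, 50-frame/30 s timelapse) triples; percent
  recovery = normalized(final) − normalized(first post-bleach frame)
  estimates the mobile fraction *m*(1 − e^(−kT)).
- **Two-channel statistics** — voxelwise Pearson correlation over the
  union of the channel foregrounds, and the relative positional variance
  rpv = σ²/µ of the distances from one channel's foreground voxels to the
  other channel's intensity-weighted center (≈ 0 for a shell, R/20 for a
  filled ball of radius R).
- **Group statistics and batch orchestration** — Wilcoxon rank-sum and
  ANOVA + Tukey HSD comparisons; `runBatch()` drives any analysis over a
  manifest CSV with per-record failure logging and byte-reproducible
  outputs.
- **Synthetic data** — ground-truthed generators for both condensate
  regimes, shell/intermixed two-channel geometries and FRAP kinetics, so
  every stage is testable without real acquisitions.

## Worked example

```r
library(nucleoquant)

# a compacted polymer condensate with known ground truth
g <- generatePPPS(crosslinkDensity = 0.7, seed = 7)
g$stack
#> VoxelStack [z=19, y=55, x=55] channel='synthetic-ppps'
#>   voxel size (dz,dy,dx) = (0.3, 0.0636, 0.0636) um
#>   intensity range [0, 1035]

signalMetrics(g$stack)
#>   volume mean_above_bg compression heterogeneity integrated_intensity
#> 1    272      243.7381      0.8961        0.2245             136643.6
#>   in_focus_area max_proj_area sum_proj_area threshold
#> 1           130           132           121  258.6279

homogeneityScore(g$stack)$score
#> [1] 0.5856
```

272 voxels at a mean of 244 intensity units above background give a high
compression of 0.90 — the signature of a tight, dense signal — and the
sharp puncta pull texture homogeneity down to 0.59 (a flat droplet of the
same integrated intensity scores ≈ 0.71).

```r
# FRAP with a 50% mobile fraction under gentle photobleaching
fr <- generateFRAP(m = 0.5, k = 0.3, beta = 0.01, seed = 7)
normalizeWithCorrection(fr$experiment)
#> RecoveryCurve: 50 frame(s), percent recovery 0.4888 (unrecovered 0.5008)
#>   bleach rate -0.520282 intensity/frame, correction 'ratio'

# shell geometry: rDNA excluded to the nucleolar surface
tc <- generateTwoChannel("shell", radius = 10, seed = 7)
fa <- filterStack(tc$channelA); fb <- filterStack(tc$channelB)
relativePositionalVariance(fa, signalCenter(fb), units = "voxel")$rpv
#> [1] 0.064
channelCorrelation(fa, fb)$pearson_r
#> [1] -0.356
```

The measured percent recovery 0.489 matches the simulated plateau
m(1 − e^(−kT)) = 0.5 × (1 − e^(−0.3·29.4)) ≈ 0.500; the shell's near-zero
rpv (0.06 voxels vs 0.50 for an intermixed ball) and negative channel
correlation are the positional signature of surface exclusion.

Batch runs over directories of TIFF crops use a manifest CSV
(`id, group, path[, path_channel2 | prebleach, laser, timelapse]`):

```r
runBatch(list(analysis = "homogeneity", manifest = "manifest.csv",
              out = "results/", seed = 1))
```

or the equivalent command-line wrapper
`Rscript inst/scripts/nucleoquant.R homogeneity --manifest manifest.csv --out results/`.

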