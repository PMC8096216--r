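---
title: "Methods: quantifying polymer versus liquid condensates from fluorescence stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying polymer versus liquid condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(nucleoquant)
```

# The measurement problem

Two assembly mechanisms produce visually similar nuclear bodies but behave
differently under perturbation. A liquid–liquid phase-separated (LLPS)
droplet maintains a fixed internal concentration: material added to the
dense phase grows the droplet. A polymer–polymer phase-separated (PPPS)
condensate — a chromatin domain held together by crosslinks, such as the
budding-yeast rDNA array — conserves its material: adding crosslinks
compacts it, shrinking volume while raising concentration. `nucleoquant`
turns this dichotomy into measurements on cropped single-signal z-stacks:

* within one cell: texture homogeneity, compression, heterogeneity;
* across a population: the sign of the volume–concentration correlation;
* dynamics: FRAP percent recovery (mobile fraction);
* two-channel geometry: Pearson correlation and relative positional
  variance (shell-like exclusion vs intermixing).

All analyses assume a *single* signal per crop (no instance segmentation),
non-negative intensities, and that background and signal are separable by
a global per-stack threshold. Deconvolved, chromatically registered input
is assumed; the package performs no registration or flat-field correction.

# Segmentation

Each stack (or projection, for the texture path) is thresholded by
single-level Otsu: the split of the intensity histogram maximizing
between-class variance. Voxels strictly above the threshold are
foreground; ties at the threshold are background, the deterministic
equivalent of "set sub-threshold voxels to NaN". Numerical conventions:

* data with at most 256 distinct values (any 8-bit image, most 16-bit
  crops) use one histogram bin per value, so the optimum is exact over the
  empirical distribution; the returned threshold is the midpoint of the
  gap between the optimal classes, which makes the foreground mask
  identical under any affine intensity map and keeps the threshold
  strictly between the two classes of a bimodal image;
* richer data fall back to 256 equal-width bins over [min, max] with the
  threshold at the separating bin edge;
* criterion ties break toward the smallest threshold;
* constant images raise an error — a constant crop indicates an upstream
  mistake, and in batch mode the failure is logged per record rather than
  propagated.

Population analyses threshold each stack independently; no threshold is
shared across images.

# Texture homogeneity

The stack is collapsed to a sum-intensity projection (`mode = "max"` is
available; sum is the default and the convention used throughout), the
projection is Otsu-thresholded, and valid pixels are min–max rescaled to
[0, 1]. Rescaled values are quantized to the integers 1..8 by
round-to-nearest scaling, `level = floor(x * 7 + 0.5) + 1` — the
convention of the standard gray-level co-occurrence routines, under which
0 maps to 1, 1 to 8 and 0.5 to 5. The co-occurrence matrix counts pairs at
the single offset (0, +1) (horizontally adjacent), skips any pair touching
an invalid pixel, and is not symmetrized; `n_pairs` bookkeeping therefore
refers to ordered pairs, which the score is insensitive to. The score

$$H = \sum_{i,j} \frac{p(i,j)}{1+|i-j|}, \qquad p = \mathrm{counts}/n_\mathrm{pairs}$$

is 1 exactly when all adjacent pairs share a level, and 1/8 for a strict
checkerboard of levels 1 and 8. A constant foreground (degenerate rescale)
is assigned the limiting score of exactly 1 instead of erroring, so
degenerate but real cells are not dropped from batch runs. The score is
invariant under affine intensity maps (absorbed by rescaling) and under
left–right mirroring (|i − j| is symmetric).

# Morphometry and the population correlation

Per signal, from the stack-level threshold $t$ and foreground of volume
$V$ voxels: mean intensity above background
$\bar I = (\sum_{\mathrm{fg}} I)/V - t$ (concentration proxy), compression
$\bar I / V$ (intensity·voxel⁻¹), heterogeneity = population SD of the
min–max rescaled foreground (bounded by 0.5, reached by a half-min /
half-max signal; sample SD is available via `sdType`), integrated
intensity, in-focus area (above-threshold pixels of the z-plane with the
greatest integrated intensity), and max/sum-projection areas (each above
its own projection-level Otsu threshold).

Population volume–intensity correlation uses Pearson's r with the
two-sided p-value from the t-transform on n − 2 degrees of freedom.
Because Pearson's r is outlier-sensitive, records are first gated: a
record is excluded when any of six measures (volume, in-focus area, max-
and sum-projection areas, integrated intensity, mean above background)
deviates from its population median by more than 3 scaled median absolute
deviations (1.4826 × MAD; when the MAD is zero, any deviation from the
median counts). Gating is performed per analyzed group, since groups are
analyzed separately throughout.

# FRAP

An experiment is the triple (pre-bleach image, laser-spot image,
timelapse). The monitored region is the intersection of the Otsu
foregrounds of the pre-bleach and laser images; its mean pre-bleach
intensity anchors normalization. Frame times default to uniform spacing,
duration/n (0.6 s for 50 frames over 30 s).

Imaging-induced photobleaching is estimated as the least-squares slope
(intensity per frame) of a reference trace — by default the mean over the
non-bleached signal (pre-bleach foreground minus the recovery region),
which tracks the loss at the signal's own intensity scale; a whole-frame
mode exists. The reported `bleach_rate` is always this raw slope. The
default correction is *ratio*: each region mean is divided by the fitted
relative trend $(a + b i)/a$ of the reference trace. Photobleaching acts
multiplicatively (a constant per-frame survival probability), so a
proportional correction is unbiased for any recovery level, whereas adding
a fixed $|b| i$ — the `additive` mode, also provided — over-corrects weak
recoverers and under-corrects strong ones by an amount proportional to the
difference between the reference intensity and the recovered intensity.
If percent recovery still comes out negative (possible when noise or
residual bleaching dominates a near-immobile signal), the applied
correction magnitude is increased by 10% per iteration, capped at 100
iterations, until it is positive; `rate_adjusted` and the iteration count
are always reported.

Percent recovery is normalized(final frame) − normalized(first post-bleach
frame). With complete bleaching and no photobleaching this equals
$m(1-e^{-kT})$ exactly at the final frame time $T$; with incomplete
bleaching it scales by $1 - I_\mathrm{post}/I_\mathrm{pre}$. The
complementary quantity 1 − normalized(final) is reported as
`unrecovered_fraction` alongside, since the literal "pre-bleach minus
final frame" difference measures non-recovery rather than recovery; both
are emitted so either convention can be compared across groups. No
diffusion-model fitting or half-time estimation is attempted.

# Two-channel statistics

`channelCorrelation` computes Pearson's r over the *union* of the two
foreground masks using raw intensities: thresholding defines support only.
The union deliberately retains exclusion zones — voxels where one signal
is present and the other absent — which are the phenomenon of interest for
shell-like geometries and which an intersection rule would hide.

`signalCenter` is the intensity-weighted centroid of the foreground
(mask centroid available), robust to threshold jitter. The relative
positional variance takes the Euclidean distances from every foreground
voxel of channel A — each voxel counted once, regardless of intensity (an
intensity-weighted variant is exposed but is not the reference
definition) — to the reference center, and reports
$\mathrm{rpv} = \sigma^2/\mu$ (population variance by default). Distances
are computed in physical micrometres using the voxel size by default,
which handles anisotropic grids; `units = "voxel"` matches the physical
mode exactly on isotropic unit grids. rpv has units of length and scales
linearly under isotropic rescaling: ≈ 0 for a thin shell, $R/20$ for a
uniform ball of radius $R$ (density $3r^2/R^3$ gives $\mu = 3R/4$,
$\sigma^2 = 3R^2/80$).

# Group statistics and batch runs

Two-group comparisons use the two-sided Wilcoxon rank-sum test (normal
approximation with tie correction); three or more groups use one-way ANOVA
followed by Tukey HSD, with all pairwise adjusted p-values reported and
the omnibus F always shown alongside rather than used as a gate.
`runBatch` echoes its full configuration (every option has a recorded
default), logs per-record timing and failures without aborting, and is
byte-deterministic given (config, seed).

# The synthetic generators

The generators exist to give every stage ground-truthed input; they
embody the regime definitions rather than any fitted optics model.

* **LLPS**: a sphere of fixed concentration (default 80 intensity units)
  and prescribed voxel volume (default 2000) at a random interior
  position. The sphere is defined in physical micrometres — default voxel
  size 0.3 × 0.0636 × 0.0636 µm, i.e. the 55 px = 3.5 µm crop convention
  in-plane with a typical 0.3 µm z-step — so it appears as an oblate voxel
  ellipsoid, as real droplets do. The default stack is 19 × 55 × 55
  (z, y, x): deep enough to hold a 4000-voxel droplet with a 2-voxel
  margin.
* **PPPS**: n Gaussian blobs (default 6) placed uniformly in a bounding
  sphere; the bounding radius (0.9 µm × (1 − 0.75 d)) and blob width
  (0.28 µm × (1 − 0.6 d)) shrink with the crosslink-density parameter
  d ∈ [0, 1], while the integrated intensity is rescaled after blurring to
  a conserved total (default 2 × 10⁵) — compaction with conservation.
* **Two-channel**: channel B a uniform ball (default R = 10 voxels,
  isotropic 0.1 µm voxels so voxel-unit dispersion fixed points apply);
  channel A either fills the ball (intermixed) or forms a shell of default
  thickness 1.5 voxels at its surface. The intermixed A fills B uniformly
  precisely so the uniform-ball rpv = R/20 fixed point holds; the Pearson
  separation between geometries then comes from the blurred boundary
  (default blur 1 voxel): intermixed edge gradients co-vary, a shell peaks
  where the ball declines.
* **FRAP**: disk-shaped signal (radius 14 px at 100 intensity units, the
  bleach spot of radius 5 px inside it), 50 frames over 30 s; the region
  recovers as $[I_\mathrm{post} + m(I_\mathrm{pre}-I_\mathrm{post})
  (1-e^{-kt})]e^{-\beta t}$ while the rest of the signal decays as
  $I_\mathrm{pre}e^{-\beta t}$. The default bleach depth is complete
  ($I_\mathrm{post}=0$), the regime in which percent recovery estimates
  $m(1-e^{-kT})$ directly.

Shared choices: Gaussian noise with SD 5% of the foreground intensity
(2% for FRAP frames, where the measured quantity is a mean over ~80
pixels); a Poisson mode for realism stress-tests. The point-spread blur
(default 0.5 voxel for the single-channel generators) is applied in-plane
only: the emulated stacks are deconvolved and coarsely sampled in z, where
a z-blur would mostly couple the few planes artificially. Signal pixels
take their model values directly and the background level fills the
remainder, so construction identities (droplet mean = concentration,
FRAP region intensity = the kinetic model) hold exactly at zero noise.
Every generator accepts a seed and is bit-reproducible from (parameters,
seed) without disturbing the caller's RNG stream, and reports all
realized quantities (volume, integrated intensity, centers, expected
recovery) in its ground-truth record.

What the generators do *not* emulate: spatially varying background,
camera gain and offset, z-dependent attenuation, chromatic misregistration,
neighbouring signals in the crop, or polymer dynamics (no bead–spring
simulation). Passing tests therefore demonstrate correctness of the
*measurements* under the stated geometric and kinetic models, not
robustness to every artifact of real acquisitions.

# Problem sizes and empirical behavior

The test suite and the acceptance script run the population analyses at
the scales the statistics are designed for: 200 stacks per regime for the
correlation dichotomy (crosslink density ~ U(0.2, 0.9); droplet volume ~
U(500, 4000) voxels), 100 + 100 matched-intensity stacks for the
homogeneity comparison, 50 crosslink-density levels for the compression
sweep, 50–100 two-channel pairs for the dispersion fixed points, and 20
replicates per condition for the FRAP grid (m ∈ {0.1, 0.5, 0.8},
β ∈ {0, 0.01} s⁻¹). At these sizes the polymer regime shows
r(V, Ī) ≤ −0.8, the liquid regime |r| ≤ 0.2, droplets out-score puncta in
homogeneity at rank-sum p < 0.001, compression tracks ground-truth
density at Spearman ρ > 0.9, the intermixed ball reproduces rpv = R/20
within ±0.05 voxels with shells below intermixed in every pair, and FRAP
percent recovery lands within ±0.05 (no bleaching) or ±0.1 (β = 0.01) of
the simulated plateau.

# Known limitations

* **Otsu edge bias.** On blurred droplets the threshold creeps upward
  with droplet size (edge-ramp voxels add intermediate-intensity
  histogram mass), inducing a weak systematic volume-dependence of the
  measured mean above background: |r| ≈ 0.2 at n = 200 under the default
  0.5-voxel blur, vanishing at zero blur. Any global-threshold pipeline
  shares this bias; it is small relative to the PPPS signature
  (r ≤ −0.8) but worth knowing when interpreting near-zero correlations.
* **Texture scores conflate compactness and count.** Homogeneity responds
  to local gray-level jumps, so a single ultra-compact blob scores *lower*
  than several overlapping diffuse ones; the discriminating comparison is
  droplet vs compact puncta (or a density sweep), not blob count.
* **The FRAP model is single-exponential** with a global linear(ized)
  bleach trend; two-component recoveries or strongly non-linear bleaching
  are out of scope, as are diffusion-equation fits.
* **One signal per crop.** Touching or multiple signals violate the
  segmentation assumption and should be excluded upstream (the MAD gate
  catches many such cases as area/volume outliers).
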