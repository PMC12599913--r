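---
title: "Detecting and comparing fluorescent puncta in straightened crops"
author: "punctakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and comparing fluorescent puncta in straightened crops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Synaptic proteins in *C. elegans* nerve cords appear in fluorescence
micrographs as chains of discrete spots ("puncta") along a thin neurite.
The unit of analysis is a *crop*: a straightened strip, typically ~20 px
tall and a few hundred px long, cut along the neurite upstream (e.g., with
Fiji's segmented-line + straighten tools) and saved as a 1-2 channel TIFF.
punctakit turns such crops into per-punctum measurements and group-level
comparisons: how many puncta, how big and bright, and -- for two-channel
crops -- how strongly the two markers colocalize.

The classical alternative, collapsing a crop to a 1D intensity profile and
counting peaks, discards the spatial structure of the spots and struggles
with dim, low signal-to-noise reporters (endogenously tagged proteins in
particular). punctakit therefore works in 2D throughout and ships the 1D
peak-finder only as a comparison baseline.

## Detection model

**Adaptive local-mean thresholding.** Each pixel is compared to the mean
$\mu_w(p)$ of the $w \times w$ window centered on it:

$$ p \in \text{foreground} \iff I(p) > \mu_w(p) \cdot 2(1 - s) $$

with sensitivity $s \in [0, 1]$ and odd window side $w \ge 3$ (default 15
px, sized to hold a punctum plus local background inside a ~20 px strip).
Because every pixel carries its own threshold, the method tolerates the
slowly varying background (imaging depth, out-of-focus gut tissue) that
defeats a single global threshold. The sensitivity enters through the
factor $2(1-s)$: $s = 0.5$ compares a pixel to its local mean, larger $s$
lowers the threshold (more permissive), and masks are *nested* in $s$ --
the exact mapping from sensitivity to threshold factor is this package's
own convention, chosen as the simplest form that is monotone, spans a
usable range over $[0,1]$, and reduces to the local mean at its midpoint.
The comparison is strict, so constant regions (including all-zero crops)
never produce foreground. Windows overhanging the crop edge are filled by
replicating border pixels, which keeps the local mean unbiased at the
edges of thin strips, where a large fraction of pixels lives.

A global Otsu threshold (256-bin, maximizing between-class variance on the
min-max normalized image) is included as the standard baseline;
`EBImage::otsu()` supplies the threshold search.

**Watershed segmentation.** Adjacent puncta frequently merge into one
thresholded component. They are split by watershed flooding on the
elevation map

$$ E = -\,(D \odot \text{normImg}) $$

where $D$ is the Euclidean distance from each foreground pixel to the
nearest background pixel (`EBImage::distmap()`, the same quantity as a
distance transform of the inverted mask) and normImg is the min-max
normalized channel. Multiplying distance by intensity makes both the
geometric center and the brightness peak of a punctum attract a basin, so
two touching spots of similar size but offset peaks still separate.
Flooding starts from the regional minima of $E$ inside the mask and
proceeds in order of increasing elevation (Meyer-style flooding,
implemented in C++); pixels where two basins meet become ridge pixels and
stay background (label 0) in the output, mirroring the convention of
labeling watershed lines with zero. Three numerical choices matter:

* a connected plateau of minimal elevation seeds *one* basin (flat-topped
  puncta are not over-segmented);
* ties in elevation are broken first-in-first-out, making the flood -- and
  hence every label map -- bit-reproducible;
* foreground components and minima both use 8-connectivity.

Per-crop min-max normalization was preferred over dataset-level
normalization because crops differ in exposure context; the elevation map
only needs relative intensity within one crop.

## ROI restriction and measurement

Detected ROIs pass two families of filters, evaluated independently per
ROI (so filtering is order-free and idempotent):

* **Edge exclusion.** An ROI is removed if *any* of its pixels falls
  within `xEdge` / `yEdge` pixels of the crop edges. The any-pixel rule
  (rather than a centroid rule) is deliberate: the typical offender is an
  autofluorescent gut granule impinging on the strip from outside, which
  merely touches the edge band. A y-edge margin of 3 px is the working
  setting for 63x data (~0.63 um at 0.21 um/px).
* **Feature bounds.** Optional min/max bounds on area (px^2), circularity,
  length-to-width ratio, and within-ROI intensity variance. The default
  enables only a minimum area of 5 px^2 (0.22 um^2 at 0.21 um/px), which
  suppresses single-bright-pixel noise. The variance filter is
  double-bounded and off by default, since a useful direction depends on
  the reporter.

Feature definitions, where conventions were needed:

* circularity $= 4\pi A / P^2$ with $P$ counted as 4-connected boundary
  edges (between an ROI pixel and anything else); a single-pixel ROI is
  *defined* to have circularity 1 rather than dividing by a tiny
  perimeter;
* length-to-width ratio is the square root of the eigenvalue ratio of the
  pixel-coordinate covariance matrix with $1/12$ added to the diagonal
  (the variance of a unit pixel), so a $1 \times n$ bar scores exactly $n$
  and a single pixel exactly 1, with no degenerate zero-width case;
* intensity variance is the population variance (0 for single pixels);
* crop-level summaries: ROI count, count per 100 um of crop length
  ($n / (L_{px} \cdot s_{um/px}) \cdot 100$), and SNR defined as summed
  intensity inside ROIs over summed intensity outside.

## Colocalization metrics

Three families, for two-channel crops:

* **PCC** -- Pearson correlation of the two channels over *all* crop
  pixels. No mask is applied: cropping itself is the step that minimizes
  unrelated background. For noise comparisons it is rescaled to $[0,1]$ as
  $(\mathrm{PCC}+1)/2$, making its range comparable with the other two
  metrics.
* **Binary Manders coefficients** -- $M_1 = |S_1 \cap S_2| / |S_1|$ and
  symmetrically $M_2$, computed on the post-restriction signal masks with
  binary indicators. This is deliberately the pixel-count form, not the
  classic intensity-weighted Manders definition.
* **ROI Overlap Ratios** -- object-level: ROI $a$ of channel 1 counts as
  colocalized iff the fraction of its pixels that are signal in channel 2
  is $\ge \theta$ *and* positive; $R_1$ is the colocalized fraction of
  channel-1 ROIs, $R_2$ the reverse direction. The inclusive comparison
  plus the positivity guard means $\theta = 0$ reads as "any overlap at
  all", and $R_1(\theta)$ is non-increasing with exact endpoint semantics
  ($\theta = 1$: fully covered ROIs only). The overlap is evaluated
  against the other channel's post-restriction label support, so both
  channels have passed identical pipelines; the default
  $\theta = 0.3$ sits in the range where object-level assignments are
  stable for well-overlapping markers.

The division of labor: Manders coefficients resolve *within-structure*
composition changes (e.g., an active-zone marker occupying a sub-region
of a vesicle-filled bouton), while the overlap ratios answer the binary
*same-structure-or-not* question per punctum and ignore small boundary
overlaps of adjacent objects.

## Validation toolkit

* **Confusion rates** against a ground-truth mask: TPR (fraction of truth
  ROI pixels recovered), TNR (fraction of truth background kept clean),
  and balanced accuracy $(\mathrm{TPR}+\mathrm{TNR})/2$, exactly. The
  `column1d` mode first collapses both masks column-wise (a column is
  positive if it holds any ROI pixel) -- the only fair mode for 1D
  profile baselines.
* **1D peak-finder baseline**: column-sum profile, strict local maxima
  (plateaus count once, at their middle), filtered by prominence, width at
  half prominence, and a height floor expressed as a multiple of the
  profile median. That last filter implements the baseline's
  "noise-to-signal" control; tying it to the median is this package's
  choice, as the quantity only needs a robust scale for the profile
  background. Each peak claims its half-prominence column interval, which
  converts a peak list into a column-mode mask.
* **Sensitivity sweep**: the full pipeline re-run over a sensitivity grid
  (optimum $\pm 0.15$ in steps of 0.01 -- an interval of 0.3 out of the
  possible 0-1), recording per-crop counts and a Welch one-way ANOVA
  p-value per grid point. When the Welch statistic is undefined (a
  zero-variance group), the pooled-variance ANOVA is the fallback, and
  coincident group means report $p = 1$, separated point masses $p = 0$.
  Post-hoc pairwise comparisons are delegated to standard routines
  (`pairwiseWelch()` wraps Welch t-tests with Holm adjustment); a
  dedicated unequal-variance multiple-comparison procedure was left to
  external statistics software, which is where such comparisons are
  typically finished anyway.

## The synthetic generator and what it does (not) emulate

`generateScene()` builds a strip (default 20 x 500 px at 0.21 um/px,
matching the 20-px tracing width) with isotropic Gaussian puncta along the
strip mid-line over a constant background (default 0.1) plus Gaussian read
noise, clipped at zero. Ground truth for punctum $k$ is its half-maximum
footprint -- the pixels where its noiseless contribution reaches half its
amplitude -- which is a *convention*, needed because real ground truth is
hand annotation and a synthetic truth must be defined somehow. Optional
"edge confounders" mimic gut granules: bright blobs centered within 3 px
of the y-edges that appear in the image but never in the truth, so edge
exclusion can be exercised against a known target.

Default study conditions (chosen once, used by the tests and the
acceptance script):

* high-SNR, overexpressed-like scenes: amplitudes 0.5-1.0 on background
  0.1, read noise SD 0.02, sigma 1.5-2.5 px, minimum separation 12 px;
  detection tuned at sensitivity 0.1-0.2, window 15;
* dim, endogenous-like scenes (for robustness studies): amplitudes
  0.25-0.45, read noise SD 0.04 -- at these levels detection is clean at
  the tuned sensitivity but permissive settings start admitting noise
  clusters, which is the regime where robustness questions are
  interesting;
* synthetic phenotypes: severe = 3 puncta/crop at half amplitude, mild =
  9 puncta/crop at ~8% lower amplitude, vs. 12 puncta/crop controls,
  n = 15 crops per genotype, 300 px crops.

Noise injection (`addNoise()`) follows the conventions of standard image
noise utilities: the image is min-max rescaled to $[0,1]$, noise applied,
clipped to $[0,1]$, and mapped back. Gaussian (additive, mean/variance),
speckle (multiplicative zero-mean uniform of given variance), and
salt-and-pepper (a fraction `density` of pixels sent to the extremes,
half each way) are parameterized on that scale, with the usual grids
(mean/variance up to 0.2, density up to 0.05). Poisson noise needs a
counts scale -- a Poisson law on $[0,1]$ intensities is ill-posed -- so
intensity 1 maps to `poissonScale` counts (default 1000, roughly an EMCCD
well at moderate gain); this scale is a documented choice.

What the generator does *not* emulate: optical PSF shape (puncta are
ideal Gaussians), structured background (gradients from the gut or body
curvature), z-projection artifacts, pixel-correlated camera noise, and
annotator variability in the ground truth. Passing the end-to-end
recovery tests therefore demonstrates the pipeline's correctness and
stability under controlled conditions, not its accuracy on any particular
real dataset.

## Problem sizes

The shipped test-suite and acceptance-script sizes: 200 random 20 x 60
images for the thresholding oracle; 50 merged two-punctum scenes plus 50
single blobs for watershed; 100 random label maps for the restriction
oracle; 100 high-SNR crops for count/footprint recovery; 50 scenes x 7
noise settings for the metric robustness study; and 15 + 15 crops per
genotype with 20 replicate datasets for the robustness sweep. These sizes
give stable stochastic margins while a full run stays in the minutes
range on one CPU.

## Known limitations

* 2D only; z-stacks must be projected upstream, and at most two channels
  per crop.
* The sensitivity-to-threshold mapping is this package's own (monotone,
  midpoint-at-local-mean) convention; per-pixel mask equality with other
  local-means implementations is not claimed.
* Writing non-integer intensities to TIFF quantizes to a min-max scaled
  32-bit unsigned grid (~2e-10 relative precision), because the TIFF
  writer used has no float sample format; integer-valued data (the common
  acquisition case) round-trips exactly.
* At sensitivity 0.5 the threshold equals the local mean, so on pure-noise
  background about half the pixels cross it; sweeps that reach 0.5 measure
  the restriction filters as much as the threshold.

## A worked session

```{r}
library(punctakit)

# simulate a small control-vs-mutant study
ds <- generateSceneDataset(
  list(control = list(nPuncta = 12), mutant = list(nPuncta = 5)),
  nCrops = 10, seed = 1, width = 300
)

cfg <- AnalysisConfig(
  detection = DetectionParams(sensitivity = 0.2, neighborhood = 15),
  restriction = RestrictionParams(yEdge = 3, minArea = 5),
  pixelSize = 0.21
)

res <- runPipeline(ds$dataset, cfg, outDir = "analysis_out")
head(res$summary)

# was the conclusion robust to the sensitivity setting?
sw <- sensitivitySweep(ds$dataset, cfg)
plot(sw$anova$sensitivity, -log10(sw$anova$p_value), type = "b",
     xlab = "sensitivity", ylab = "-log10 p (Welch ANOVA)")
```
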