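# punctakit

Detection, restriction and colocalization of fluorescent puncta in
straightened neurite crops.

## What problem this solves

Fluorescence images of *C. elegans* nerve cords show synaptic proteins as
chains of discrete puncta along a thin axon. The common unit of analysis is
a *crop*: a straightened ~20-px-wide strip traced along the neurite and
saved as a 1-2 channel TIFF. Counting and measuring these puncta is usually
done either by hand or with 1D intensity-profile peak counting -- both hard
to reproduce, and both fragile for dim endogenous reporters with low
signal-to-noise ratios.

punctakit is a scriptable 2D pipeline for that job, aimed at anyone who
quantifies punctate fluorescence along neurites (or similar thin
structures) and wants batch, deterministic, parameter-explicit analyses:

1. **Detection** -- adaptive local-mean thresholding: pixel `p` is
   foreground iff `I(p) > mu_w(p) * 2 * (1 - s)`, where `mu_w` is the mean
   of the `w x w` window around `p` and `s` in `[0, 1]` is a sensitivity
   (higher = more permissive, masks nested in `s`). A global Otsu threshold
   is included as a baseline.
2. **Segmentation** -- touching puncta split by Meyer-style watershed
   flooding on the elevation `E = -(D * normImg)`, with `D` the Euclidean
   distance to background and `normImg` the min-max normalized channel;
   basin boundaries become ridge pixels (label 0).
3. **Restriction** -- ROIs removed by crop-edge proximity (any pixel in the
   margin band) and optional feature bounds: area, circularity
   (`4*pi*A/P^2`), length-to-width ratio (second-moment ellipse), intensity
   variance.
4. **Measurement** -- per-ROI feature table, per-crop summaries (counts,
   counts per 100 um, SNR = intensity in ROIs / intensity outside).
5. **Colocalization** (two-channel crops) -- Pearson correlation over all
   crop pixels; binary Manders coefficients `M1 = |S1 & S2| / |S1|` (and
   `M2`); and ROI Overlap Ratios `R1`/`R2`: the fraction of ROIs whose
   pixel overlap with the other channel's signal reaches an overlap
   threshold `theta`.
6. **Validation** -- TPR/TNR/balanced accuracy against ground-truth masks
   (pixel or column mode), a 1D sum-projection peak-finder baseline, a
   sensitivity robustness sweep with Welch ANOVA per grid point, and a
   four-model noise study (Poisson, Gaussian, speckle, salt-and-pepper).
7. **Synthetic data** -- a generator for strip-shaped scenes with known
   ground truth (Gaussian puncta, read noise, optional gut-granule-like
   edge confounders), so the whole pipeline is testable without imaging
   data.

Everything is deterministic given a configuration and seed; a JSON config
replays an analysis bit-for-bit.

## Worked example

```r
library(punctakit)

# a synthetic two-genotype study: 12 puncta/crop controls vs 5 puncta/crop mutants
ds <- generateSceneDataset(
  list(control = list(nPuncta = 12), mutant = list(nPuncta = 5)),
  nCrops = 10, seed = 1, width = 300
)

cfg <- AnalysisConfig(
  detection   = DetectionParams(sensitivity = 0.2, neighborhood = 15),
  restriction = RestrictionParams(yEdge = 3, minArea = 5),
  pixelSize   = 0.21
)

res <- runPipeline(ds$dataset, cfg, outDir = "analysis_out")
head(res$summary[, c("crop_id", "genotype", "n_rois", "count_per_100um", "snr")], 4)
#>       crop_id genotype n_rois count_per_100um    snr
#> 1 control_001  control     12           19.05 0.3603
#> 2 control_002  control     12           19.05 0.3199
#> 3 control_003  control     12           19.05 0.2895
#> 4 control_004  control     12           19.05 0.3387
```

Every seeded punctum is recovered (`n_rois` = 12 for controls, 5 for
mutants; 12 ROIs over 300 px at 0.21 um/px = 19.05 per 100 um), and the
genotypes separate decisively (Welch ANOVA p ~ 0). Against the generator's
ground truth:

```r
sc <- generateScene(nPuncta = 10, amplitudeRange = c(0.8, 1), sigmaRange = c(2, 2),
                    minSeparation = 14, readNoiseSd = 0.02, seed = 42)
out <- detectROIs(channel(sc$crop), DetectionParams(0.1, 15))
tab <- measureROIs(out$labels, channel(sc$crop), 0.21)
lab <- restrictROIs(out$labels, tab, RestrictionParams(minArea = 5))$labels
max(lab)                                    # 10 of 10 puncta
confusionRates(lab > 0, sc$truth > 0)       # TPR 1.000, TNR 0.985, BA 0.993
```

`analysis_out/` contains `combined_rois.csv` (one row per ROI),
`crop_summary.csv`, `colocalization.csv` (two-channel crops), and
`manifest.json` (config snapshot + input checksums).

A command-line front end for directory-based workflows lives at
`inst/cli/punctakit.R` (subcommands `run`, `simulate`, `validate`, `sweep`,
`coloc-curve`, `noise-study`); after installation:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/punctakit.R", package = "punctakit"))')" \
  run --config cfg.json --in crops/ --out out/
```

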