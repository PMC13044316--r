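# vesiclust

Quantification of late-endosome/lysosome (LE/Lys) clustering in
fluorescence microscopy images, built around a per-cell **clustering
index** and validated end to end on synthetic scenes with known ground
truth.

## The problem

The intracellular position of LE/Lys is regulated: under some
perturbations (e.g. GSK3 inhibition, or expression of membrane-contact
proteins whose phospho-motif cannot be phosphorylated), vesicles that are
normally scattered through the cytosol collapse into tight perinuclear
clusters. A simple, robust readout of that phenotype is the per-cell

```
clustering index = (# vesicles in direct contact with >= 1 other vesicle) / (# vesicles in the cell)
```

where "direct contact" is defined on segmented label masks by 8-connected
pixel adjacency (with a configurable 1-pixel grace). Dispersed cells sit
around ~0.4 on this index; clustered cells around ~0.7. Per-cell values
are nested in independent experiments, so statistics follow the superplot
convention: small dots per cell, large dots per experiment, one-way ANOVA
with Tukey (or Dunnett) comparisons.

The package is for cell biologists and image analysts who want this
quantification as a reproducible, scriptable pipeline — and for anyone who
wants to test such a pipeline without real images: a synthetic scene
generator renders fields of cells with vesicles placed at a *known*
contact fraction, so every stage can be checked against a geometric
oracle.

## What's inside

| Stage | Functions |
|---|---|
| Synthetic scenes | `sceneSpec()`, `makeScene()`, `renderScene()`, `truthContactFraction()`, `makeColocPair()` |
| Segmentation | `maxProject()`, `segmentCells()`, `detectVesicles()` |
| Contact quantification | `assignToCells()`, `buildAdjacency()`, `clusteringIndex()` |
| Colocalization | `pearsonR()`, `costesThresholdedPearson()`, `colocTable()` |
| Superplot statistics | `aggregateSuperplot()`, `studentsT()`, `oneWayAnova()`, `tukeyHsd()`, `dunnettMC()` |
| Orchestration & I/O | `runPipeline()`, `readImageTiff()`, `writeImageTiff()`, `readRunConfig()` |

Vesicle segmentation is a weight-free classical detector (multiscale
Laplacian-of-Gaussian markers, distance-transform neck test, seeded
watershed) so the whole pipeline is deterministic and self-contained;
externally produced cell masks can be injected via
`segmentCells(suppliedMask = ...)`.

## Worked example

```r
library(vesiclust)

res <- runPipeline(list(
  seed = 1, experiments = 2, cellsPerExperiment = 10,
  conditions = list(
    list(name = "control",   preset = "dispersed"),
    list(name = "clustered", preset = "clustered")),
  logLevel = "quiet"))

res$summary$experiment
#>   condition      mean           sd n sd_defined
#> 1 clustered 0.7018118 5.420331e-04 2       TRUE
#> 2   control 0.4028920 4.927573e-05 2       TRUE

res$comparisons[, c("test", "pair", "statistic", "p", "stars")]
#>            test                 pair    statistic            p stars
#> 1 one-way ANOVA    control,clustered 2.466854e+04 4.591666e-55  ****
#> 2     Tukey HSD control vs clustered 2.989199e-01 0.000000e+00  ****
```

Each condition is generated at its calibrated ground-truth contact
fraction (0.4 dispersed, 0.7 clustered), rendered with a Gaussian PSF and
Poisson-Gaussian camera noise, segmented, and quantified; the summary
shows the pipeline recovering both regimes, and the ANOVA/Tukey stage
reports the condition contrast with the four-tier star coding.

A command-line wrapper with `simulate`, `segment`, `quantify`, `coloc`,
`stats` and `pipeline` subcommands lives at
`system.file("cli/vesiclust.R", package = "vesiclust")`.

## Documentation

The methods vignette (`vignettes/vesicle-clustering-methods.Rmd`) explains
the scene model, the segmentation design, the adjacency rule, the Costes
threshold emulation, the superplot statistics, and every tunable
parameter with its default and rationale.
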