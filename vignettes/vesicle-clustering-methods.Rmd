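---
title: "Quantifying vesicle clustering: models, parameters and design choices"
author: "vesiclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vesicle clustering: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiclust)
```

## The statistic and its rationale

Late endosomes/lysosomes (LE/Lys) respond to signalling perturbations by
changing position: from a dispersed cytosolic distribution to compact
perinuclear clusters. `vesiclust` quantifies this with a per-cell
**clustering index**: the proportion of segmented vesicles in direct
contact with at least one other vesicle of the same cell. The index is a
pure proportion — robust to vesicle number, cell size and intensity
scale — and separates the two biological regimes cleanly: dispersed cells
sit near 0.4 (occasional incidental contacts), clustered cells near 0.7.

"Direct contact" on pixel masks follows the adjacent-objects neighbour
rule: labels are neighbours when their supports touch under 8-connectivity
after a configurable expansion. `buildAdjacency(mask, expandPx)` connects
two labels iff the minimum Chebyshev distance between their pixel sets is
at most `2*expandPx` (or 1 when `expandPx = 0`). The default
`expandPx = 1` — touching or separated by one background pixel — absorbs
the one-pixel quantization jitter of segment boundaries; the original
neighbour-distance parameter used in published analyses of this kind is
typically unreported, so it is exposed as a flag and its effect can be
measured directly.

Two further conventions are deliberate:

* **Inter-cell contacts are discarded.** The index is defined per cell; a
  vesicle touching only a neighbouring cell's vesicle counts as
  non-contacting.
* **Cells with fewer than two vesicles are undefined**, not zero. A
  proportion over one object carries no information and would bias
  condition means downward.

## The synthetic scene model

Real validation data for a contact statistic barely exist: manual
annotation of "touching" at the diffraction limit is itself the
uncertainty. The generator therefore *constructs* scenes whose contact
structure is known exactly, and the pipeline is judged on recovering it.

A `SceneSpec` fixes all parameters. A scene contains star-convex cell
blobs on a near-square jittered grid (radius wiggle ±12%, one nucleus disk
of 0.22 cell radii each), and per cell a set of vesicle disks:

* a **clustered fraction** `f` of vesicles placed into touching chains —
  consecutive members at center distance exactly `r_i + r_j` (boundary gap
  0, overlap capped at 1 px so the blob stays segmentable), chain length 4
  in the clustered preset, 2 for incidental pairs;
* the rest **isolated**, with boundary gap at least `minIsolatedGap = 6`
  px to every other vesicle — strictly above the adjacency tolerance, so
  "isolated" is unambiguous in both the geometric and the pixel domain.

Because chains have length ≥ 2, the geometric ground-truth index of a cell
is exactly (number of chain members)/(number of vesicles);
`truthContactFraction()` computes it from disk geometry (disks touch iff
center distance ≤ `r_i + r_j + tolPx`, `tolPx = 1` mirroring the pixel
rule) and the construction-soundness property is tested across `f` from 0
to 1.

The two presets encode the study conditions:

| preset | `clusteredFraction` | chains | placement | truth index |
|---|---|---|---|---|
| `dispersed` | 0.4 | pairs | uniform in cell | 0.4 |
| `clustered` | 0.7 | chains of 4 | perinuclear (≤ 0.3 cell radii of the nucleus, widening only under congestion) | 0.7 |

Values not determined by the regimes are engineering choices, made once:
512×512 px fields, 5 cells per field, 40 vesicles per cell with radii
drawn uniformly from 3–5 px. These are plausible for a ~100× confocal
acquisition of cultured cells downsampled to analysis resolution; nothing
downstream depends on them beyond feasibility of placement (infeasible
geometry raises an explicit "placement infeasible" error rather than
silently dropping vesicles).

**Rendering.** Vesicles are uniform disks (pixel inside iff center
distance < r) at peak intensity 1 over a 0.05 background, convolved with
a Gaussian PSF (σ = 1 px default), then corrupted by Poisson photon noise
(50 photons per intensity unit) and additive Gaussian read noise
(SD 0.02). `photonScale = 0, readNoiseSd = 0` turns rendering fully
deterministic for oracle tests. Convolution is intensity-conserving (the
integral above background stays within 0.5% of disk area × peak, a tested
invariant).

**What the generator does not emulate:** 3-D anisotropic PSFs (scenes are
generated directly in the projected plane), intensity heterogeneity
within and between vesicles, organelle crowding by other structures,
autofluorescence gradients, and true optical sectioning. Passing tests
therefore demonstrate that the *quantification machinery* is correct and
unbiased on geometry it can see — not that segmentation of any particular
real dataset is accurate. For real data the mask-injection path
(`segmentCells(suppliedMask=)`, label-mask TIFF input) keeps the
quantification applicable behind any segmentation a user trusts.

## Segmentation design

The reference workflow this replaces used a learned star-convex detector
plus manually drawn cell outlines; neither is reproducible from a methods
description alone. `vesiclust` substitutes fully specified classical operators,
validated against scene truth (recall and precision ≥ 0.95 on clean
renders, a tested invariant):

1. **Background**: grayscale morphological opening with a disk of radius
   `4*maxRadiusPx`, subtracted; scale-free and flat for structures smaller
   than the brush.
2. **Foreground**: Otsu threshold of the residual (computed on the
   range-normalized image, so segmentation is invariant under uniform
   intensity rescaling — tested).
3. **Markers**: scale-normalized Laplacian-of-Gaussian responses at
   σ = r/√2 for three radii spanning the band. Candidate markers are the
   union of *per-scale* local maxima (a coarse scale merges touching blobs
   that the fine scale still resolves) above 15% of the strongest
   response.
4. **Marker selection**: greedy non-maximum suppression, strongest first
   with a fixed column-major tie-break (so repeated runs are
   bit-identical). Two nearby candidates are both kept only if the
   foreground **distance transform necks** between them — along the
   connecting segment, the distance map must dip below 1.15× the smaller
   endpoint value. Touching disks pinch to near zero at the tangency;
   duplicate maxima inside one disk ride over its distance-map summit
   (measured separation of the two populations: pairs ≤ 1.05, singles
   ≥ 1.4, hence the 1.15 cut).
5. **Watershed**: CellProfiler-style seeded propagation of markers over
   the foreground, splitting touching vesicles at the neck.
6. **Size filter**: labels below `π·minRadiusPx²/2` are discarded —
   half the smallest expected vesicle area, rejecting noise specks while
   keeping small vesicles.

Step 4 is the step that matters for this statistic: merging a touching
pair deletes a true contact, splitting a single vesicle fabricates one,
and both biases enter the index directly. The distance-transform neck
test is what lets a single parameterization stay unbiased from fully
dispersed (truth 0) to fully clustered (truth 1) scenes — the
pipeline-vs-oracle test requires agreement within 0.05 across that whole
range, and in practice achieves ≈0 on noise-free renders.

Cell segmentation: nuclei by Otsu on the smoothed nucleus channel, hole
filling, size filter (≥ 50 px); one cell territory per nucleus by seeded
propagation on the smoothed cytoplasm channel when given, else on pure
geometric distance (Voronoi-like). A supplied mask bypasses all of it.

## Colocalization

`pearsonR()` is the plain masked Pearson coefficient (undefined — an
error, not 0 — when a channel is constant on the mask).
`costesThresholdedPearson()` emulates the automatic-threshold procedure
used by common Fiji plugins: orthogonal (major-axis) regression of
channel 2 on channel 1; a threshold `t1` walks down from the channel-1
maximum in steps of one quantization level (integers) or 1/256 of the
range (floats), with `t2 = a·t1 + b`; the walk stops at the largest `t1`
for which the below-both-thresholds pixels are uncorrelated (r ≤ 0); the
reported coefficient is Pearson over pixels above threshold in either
channel. The plain coefficient is always reported alongside, so no result
depends solely on the emulation. If the walk exhausts all candidates
(e.g. perfectly correlated channels, which never decorrelate), thresholds
are reported at the minimum with an `exhausted` flag and a warning.

The generator's `makeColocPair()` provides the calibration axis: channel
2's noiseless structure is `alpha`× channel 1 plus `(1-alpha)`× an
independent placement in the same cells, so `alpha = 1` gives pixelwise
identity, `alpha = 0` shares only background, and measured r increases
strictly with `alpha` (tested).

## Superplot statistics

Measurements are cells nested in independent experiments.
`aggregateSuperplot()` supports both conventions: per-cell pooling, and
the superplot convention — experiment means first, condition mean as the
unweighted mean of experiment means (the two differ whenever cell counts
are unbalanced; a dedicated test documents the arithmetic). Hypothesis
tests default to per-cell values, mirroring common practice in which
figure legends report per-cell n; `level = "experiment"` is available for
the conservative alternative, and with typically 3 experiments per
condition the experiment-level test is honest but low-powered — the
choice is the user's, both are first-class.

The battery: pooled-variance Student's t (degenerate zero-variance input:
p = 1 when means agree, an error when they differ), one-way ANOVA from
explicit sums of squares (F checked against a brute-force oracle to
1e-10; two-group F equals t² to 1e-8), Tukey HSD via the studentized
range on the `aov` fit (Tukey–Kramer for unbalanced groups), and
**Dunnett** many-to-one comparisons by seeded Monte Carlo of the max-|t|
null: correlated treatment-vs-control z-scores share one chi-square
variance draw, and the adjusted p is the tail frequency of the simulated
maximum (default 100,000 draws; the MC standard error is reported per
row, and adjusted p is floored at the raw p so the multiplicity
invariant holds under MC noise). The Monte-Carlo route was chosen over
distribution quadrature because it is simple, seeded-reproducible and
testable: with one treatment it collapses to the two-sided t-test within
MC error, and under a simulated global null (k = 4, n = 10) the measured
familywise error is 0.05 ± 0.01 — both are tests in the suite, and both
are cross-checked against an independent multiple-comparisons
implementation. Significance coding follows the four-tier star scheme
(\*, \*\*, \*\*\*, \*\*\*\* at 0.05, 0.01, 0.001, 0.0001).

## Numerical and degenerate-input conventions

* Coordinates are 1-based (y, x) matrix indices in pixel units throughout;
  stacks are (z, y, x).
* All ties are broken deterministically (column-major scan order), so
  every stage is bit-identical across repeated runs; all stochastic
  stages (placement, noise, Dunnett MC) are seeded, and the pipeline
  derives per-scene seeds from the config seed.
* Blank or constant images: cell segmentation returns an empty mask with
  a warning (not an exception); vesicle detection returns an empty mask
  silently; Pearson on a constant channel errors.
* Label masks are 16-bit on disk (error above 65535); intensity TIFFs
  use a [0, 1] float convention, with out-of-range images rescaled by
  their maximum on write (harmless downstream because all segmentation
  thresholds are relative).

## Problem sizes

The validation protocol runs 3 experiments × 30 cells per condition
(5-cell 512×512 fields, 40 vesicles per cell), which reproduces the 0.7
and 0.4 regimes to within ±0.01 of calibration and completes in roughly a
minute per condition on one core; the test suite uses smaller single-cell
fields (128–288 px, 3–40 vesicles) chosen to exercise each property at
the smallest size at which it is meaningful.

## Known limitations

* The classical detector is validated against synthetic truth only; its
  fidelity to any *learned* segmentation it conceptually replaces is
  unknowable without that model's weights, and real-data use should
  prefer the mask-injection path when a trusted segmentation exists.
* 2-D only: scenes model the post-projection plane; genuine 3-D contact
  geometry (and contacts lost or created by projection) is out of scope.
* The Costes emulation follows the published auto-threshold procedure;
  plugin-specific implementation details may differ in edge handling.
* Chains are built by local random walks; at extreme densities placement
  can be infeasible and errors explicitly rather than degrading.
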