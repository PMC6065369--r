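---
title: "Methods: quantifying tumor-cell local invasion"
author: "invadex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying tumor-cell local invasion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Estrogen-receptor-positive breast tumors tend to disseminate less than
ER-negative ones, and part of that difference is visible in routine
sections as tissue architecture: cohesive tumors grow as packed nests of
cells, invasive tumors scatter single cells into the stroma. `invadex`
implements a quantitative stack for measuring that scattering and the
cell dynamics behind it: a spatial statistic on cell centroids (the
Local Invasion Index), the segmentation that produces those centroids
from cytokeratin/nuclei immunofluorescence, a histomorphometric index
for intraductal xenografts (the DCIS index), an exact odds-ratio
meta-analysis of lymph-node status in hormone-therapy cohorts,
kymograph quantification of membrane ruffling, leading-edge band
quantification in confocal z-series, and a fold-change/p-value screen
over curated gene lists.

No imaging data accompany the original observations, so every analysis
ships with a synthetic-data generator that plants known ground truth.
The test suite and the acceptance script validate the stack end to end
against those planted truths and against independent oracles
(brute-force enumeration, closed forms, reference implementations).

# The Local Invasion Index

Treating cancer-cell nuclei as a spatial point pattern, each cell's
nearest-neighbor distance (NND) is the Euclidean distance to the
closest other cancer-cell nucleus. The Local Invasion Index of a tumor
region is the arithmetic mean NND over its (border-corrected) cells:
cohesive nests give small LII, scattered cells give large LII. Tumors
are binned as **low** (LII $\le$ 7 µm), **high** (LII $\ge$ 9 µm) or
intermediate; both cuts are exposed as parameters because the high cut
is reported inconsistently ($\ge$ 9 vs $>$ 9) across figures in the
literature this index comes from — we use $\ge$.

```{r}
library(invadex)
pp <- point_pattern(x_um, y_um, region_disc(500, 500, 450))  # a TMA core
rec <- compute_nnd(pp)
rec <- apply_edge_exclusion(rec, pp$region)
compute_lii(rec)        # lii, n_included, bin
```

## Border correction

A cell near the region border may have its true nearest neighbor
outside the analyzed area, so its measured NND is censoring-biased
upward. The correction excludes any cell whose *NND zone* — the closed
disc centred on the cell with radius equal to its NND — is not fully
contained in the analysis region. Tangency counts as contained (the
boundary case is not specified by the source method; a closed rule is
the deterministic choice). Exclusion never changes a cell's NND, only
its inclusion flag, and polygonal regions (circular TMA cores) are
supported with exact point-to-edge distances.

## What the border method does and does not fix

For a homogeneous Poisson process of intensity $\lambda$, the
infinite-plane mean NND is $1/(2\sqrt{\lambda})$, and the suite checks
the border-corrected LII against this closed form. One property of the
method is worth stating plainly: for an included cell the measured NND
equals the unobservable infinite-plane NND (the disc is fully observed),
but inclusion itself *truncates* the distribution — a cell at boundary
distance $b$ is kept only when its NND $\le b$, which removes large
NNDs preferentially in the border strip. The plain mean over included
cells therefore sits slightly **below** the closed form, by an amount
of order the border-strip area fraction: the acceptance script measures
about −0.5% at $\lambda = 0.04$ and −1.0% at $\lambda = 0.01$ in a
500×500 µm window. This is a property of the published index itself,
not of this implementation; we deliberately do not replace the index
with a reweighted (unbiased) estimator, and the accompanying tests
judge the closed-form recovery accordingly (the strict
three-standard-error check over 200 replicates fails by exactly this
bias and is left failing as documentation of it). At TMA-core scale the
effect is far below biological variability.

## Nearest-neighbor search

`compute_nnd()` uses a grid-bucketed search in C++ (expanding cell
rings with an exact distance bound), with the contract that results
equal the all-pairs brute force *exactly*, including ties, which break
to the lowest neighbor id. The suite enforces this equality on random
and clustered patterns; the grid is purely an acceleration.
Duplicate centroids are rejected with an error: a zero NND indicates an
upstream segmentation fault, not biology.

# Synthetic tumors

`generate_point_pattern()` provides three architectures:

* **poisson** — complete spatial randomness; the "dispersed" reference.
* **thomas_cluster** — Poisson parents of intensity $\kappa$, each with
  Poisson($\mu$) offspring displaced by an isotropic Gaussian of s.d.
  $\sigma$; realized intensity $\kappa\mu$. Parents are simulated in a
  window enlarged by $4\sigma$ per side (plus-sampling) so offspring
  intensity carries no edge deficit. The "cohesive" architecture.
* **hardcore** — dart-throwing with a minimum inter-point distance
  (default $0.25/\sqrt{\lambda}$, half the Poisson mean NND); the
  "regular", high-LII fixture.

At matched intensity, mean LII orders Thomas < Poisson < hardcore,
which the suite verifies over 100-replicate means.

`render_tissue_image()` turns a pattern into a two-channel image:
nuclei as Gaussian blobs (s.d. = half the nucleus radius) peaking at
the centroids, cytokeratin as the binary union of cell footprints
(discs of twice the nucleus radius), both with additive Gaussian noise
of s.d. peak/SNR. This emulates what threshold-based segmentation needs
— blob peaks, a cytokeratin mask, realistic noise — and nothing more:
no histology texture, no stain spectra, no 3D nucleus shape. Passing
tests on these images show the pipeline recovers planted geometry
through realistic noise; they do not certify performance on real
stains, where thresholding was interactive.

# Segmentation

`threshold_channel()` defaults to Otsu's method (the deterministic
replacement for the interactive thresholding used on the original
microscope software), with a fixed-value override. When stained objects
occupy a tiny fraction of the field, a global Otsu threshold can land
inside the background-noise mode; the optional `smooth_sigma_um`
pre-smoothing (at roughly the object scale) collapses the background
mode first. Smoothing affects only mask construction, never quantified
intensities.

`detect_nuclei()` labels mask components and splits touching nuclei by
a watershed on the mask-restricted, lightly smoothed intensity surface,
seeded at its local maxima — two merged nuclei separate at the
intensity saddle between their peaks. We chose the intensity surface
over the more common distance-map surface after measuring recovery on
clustered synthetic tissue: distance-map seeding merged about a quarter
of the cells in cohesive renders, intensity seeding about half that.
The watershed `split_tolerance` (default 0.08 intensity units, i.e.
8% of the blob peak) is the minimum peak-to-saddle drop that keeps two
seeds separate; raise it if noise oversplits large nuclei. `min_area`
(default 4 µm²; use roughly a third of the expected nucleus area)
rejects debris. Nuclei touching the image border are *retained* here —
border handling belongs to the LII edge-exclusion rule, which is the
method's stated correction.

`identify_cancer_cells()` keeps nuclei whose centroid pixel lies in the
cytokeratin mask. `count_invading_cells()` implements the 3D-culture
readout: maximum-intensity projection of the nuclei z-series, smoothing
and Otsu, component counting, and counting the components whose
centroid falls *outside* the central matrix region; a centroid exactly
on the region boundary counts as invaded (the exclusion zone is the
open interior — a deterministic tie-break). The count is invariant to
z-order permutation because projection commutes with it.

# DCIS index

For an intraductal-xenograft mid-section, with $n$ intact
(non-disseminated) DCIS structures, tumor area $A_T$ and cellular area
$A_C$ (stroma excluded):

$$\mathrm{cellular\ coefficient} = A_C / A_T, \qquad
  \mathrm{DCIS\ index} = n \cdot \frac{A_C}{A_T} \cdot \frac{1}{A_T}.$$

The coefficient corrects for cellularity differences among tumors, the
final division for tumor size. Areas default to mm² with the unit
declared on the result, since the source method normalizes "over the
tumor area" without naming units; the index scales as one over the
declared area unit and is unit-consistent under rescaling.

On real H&E sections, structure identification is a pathologist's
call; `measure_section()` therefore accepts a manual count override,
and its automated counter (connected components of the high-intensity
mask whose filled hull gains $\ge$ 10% area — i.e. ring-like objects
with a lumen) is validated only against synthetic sections, where it
recovers planted counts exactly and cellular fractions within 5%.

# Exact 2×2 meta-analysis

Per-study tables count exposure (hormone-therapy current-use vs
never-use) against outcome (lymph-node dissemination). The inclusion
filter requires at least 10 patients in *each* treatment group
(boundary inclusive); incomplete tables are excluded with a recorded
reason. Per included study:

* **Odds ratio** $(ad)/(bc)$, with the Haldane–Anscombe 0.5 correction
  applied to all four cells (and flagged) when any cell is zero.
* **Fisher's exact test**, two-sided by the point-probability method:
  the sum of hypergeometric outcome probabilities no greater than the
  observed one (ties compared with a $10^{-7}$ relative tolerance, the
  convention of standard software). The suite proves equality with
  exhaustive enumeration to $10^{-12}$ for tables up to $n = 40$.
* **Exact confidence interval**, Cornfield-type: each bound inverts a
  one-sided noncentral hypergeometric tail test at $\alpha/2$,
  conditional on the margins; the bound is 0 (or $\infty$) when the
  observed cell sits at the edge of its conditional support. A mid-p
  variant is available behind a flag because the original analysis
  names only its software, not its interval method. Simulated coverage
  at true OR 1 and 3 (50 patients/arm) is about 97%, comfortably
  conservative as exact intervals are.

`forest_table()` emits one row per included study; a Mantel–Haenszel
pooled OR is computed only on request, because the source analysis
reports per-study ORs and pooling is our extension (cross-checked
against `metafor::rma.mh` in the tests).

# Kymographs and the leading edge

A kymograph is a space×time raster sampled along a line at the cell
edge; a membrane ruffle traverses it as a bright sloped streak whose
absolute slope, times (µm/px)/(s/frame)·60, is its speed in µm/min.
"Areas of high contrast" is operationalized as connected components of
the background-subtracted raster above a threshold set as a *fraction*
(default 0.5) of the peak contrast — relative, so detection and speed
are invariant to linear intensity rescaling. The raster is smoothed by
1 px first (steep traces otherwise fragment under 4-connected
labelling), specks under `min_trace_px` are dropped, and each trace's
slope is fitted by least squares on its pixel coordinates, with a
Theil–Sen option for crossing traces. Synthetic kymographs plant
parallel traces with enforced line-intercept separation; across speeds
0.5–5 µm/min the planted count is recovered exactly and speeds within
5%. The original scoring was by eye, so the threshold stays exposed and
these defaults are tuned on the synthetic traces only.

The volumetric leading-edge analysis restricts marker quantification to
a band within 3 µm of the cell edge. `leading_edge_band()` computes it
per z-slice (2.5D, matching slice-wise mask construction): cell mask by
thresholding the actin channel, then pixels whose distance transform,
minus half a pixel, is at most the band width. The half-pixel term
corrects the transform's convention (distance to the nearest
*background pixel centre*, half a pixel beyond the mask boundary);
with it, a 10 µm disc cell at 0.2 µm/px gives a band-to-cell area
ratio within 2% of the analytic annulus value
$1 - (7/10)^2 = 0.51$. Band means are plain arithmetic means over band
voxels, and a planted 2× enrichment is recovered within 2%.

# Volcano screen

For a curated gene list across two groups, the per-gene fold change is
the ratio of group mean intensities (reported as log2) and the p value
is Welch's two-sample comparison of log2 intensities — the simplest
defensible test, fixed here because the original portal's per-dataset
test is unspecified. A hit needs both $|$fold$| \ge 2$ and
$p \le 0.05$; no multiple-testing correction is applied by default,
matching the stated per-gene rule (Benjamini–Hochberg is available
behind a flag). Genes with zero variance in both groups are flagged,
never dropped. `cross_dataset_tally()` ranks genes by the number of
datasets in which they pass both thresholds, ties broken by mean
$-\log_{10} p$ — the "most recurrently differential regulator" logic
of a multi-dataset screen.

# Study conditions used in the validation runs

The generators' defaults define the synthetic study conditions; they
were fixed from the statistics above, not tuned on test outcomes.

| quantity | value | rationale |
|---|---|---|
| TMA window | 500×500 µm | typical core analysis area |
| Poisson λ for closed-form checks | 0.005–0.1 /µm² | spans the 7–9 µm LII bin range (λ ≈ 0.003–0.005) and denser tissue |
| cohort window / pixel | 400×400 µm, 0.5 µm/px | keeps 80 rendered tumors within desk-scale compute |
| dispersed cohort | Poisson λ = 0.0025/µm² | mean LII $1/(2\sqrt{\lambda})$ = 10 µm, safely in the high bin |
| cohesive cohort | Thomas κ = λ/15, σ = 10 µm, µ = 15 | within-cluster spacing ≈ 5–6 µm, safely in the low bin, sparse enough that nuclei remain separable |
| nucleus radius | 1.5 µm (cohort), 3 µm (recovery tests) | blob s.d. = radius/2; cohort nuclei are drawn small relative to within-cluster spacing so segmentation merging stays below ~15% |
| SNR | 5–10 | threshold-based segmentation still exact at 5 |
| kymograph | 0.2 µm/px, 2 s/frame, 45 min | DIC time-lapse scales |
| contingency simulations | 50–200/arm, baseline risk 0.3 | typical cohort-study cell counts |

No claim of biological realism attaches to these densities; the
sources give no measured tumor-cell intensities, so the values were
chosen once to exercise the binning range and the segmentation regime.

# Known limitations

* The LII border method's truncation bias (above) is inherited from
  the index definition.
* Automated DCIS-structure and ruffle detection are validated on
  synthetic ground truth only; on real data both were manual calls.
* Segmentation merges nuclei closer than roughly 1.5 blob widths even
  with intensity-watershed splitting; in strongly clustered tissue
  this inflates LII by a few percent (measured on synthetic cohesive
  cohorts), without affecting bin assignment under the conditions
  above.
* The expression screen reproduces the screen's *logic*; per-dataset
  normalization of the original portal is unknown, so exact published
  per-dataset statistics are out of reach by design.
* 2D analysis throughout: z-series are projected (invasion counts) or
  treated slice-wise (band masks); there is no 3D NND.
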