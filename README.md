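# invadex

Quantitative analysis of tumor-cell local invasion from tissue images,
with the statistics around it.

Cohesive tumors grow as packed nests; invasive tumors scatter single
cells into the stroma. `invadex` measures that scattering as the
**Local Invasion Index (LII)**: treating cancer-cell nuclei as a
spatial point pattern, each cell's nearest-neighbor distance (NND) is
the Euclidean distance to its closest neighboring cancer cell, and

> LII = mean NND over the border-corrected cells of the analyzed
> tumor region (µm)

where the border correction drops any cell whose *NND zone* — the
closed disc centred on the cell with radius equal to its NND — is not
fully contained in the analysis region. Tumors are binned as low
(LII ≤ 7 µm), high (LII ≥ 9 µm) or intermediate. For a homogeneous
Poisson pattern of intensity λ, mean NND is 1/(2√λ), which anchors the
validation suite.

Around the core statistic the package provides:

* **Segmentation** — Otsu/fixed thresholding of cytokeratin and nuclei
  channels, watershed splitting of touching nuclei, cytokeratin gating
  of cancer cells, invading-cell counting in 3D culture assays, and
  mask-restricted protein quantification (EBImage-backed).
* **DCIS index** — for intraductal xenograft sections,
  `n_structures × (cellular area / tumor area) / tumor area`,
  cellularity- and size-corrected.
* **Exact 2×2 meta-analysis** — per-study odds ratios of exposure ×
  lymph-node status with the 10-per-group inclusion filter, two-sided
  Fisher exact p (point-probability method), Cornfield exact confidence
  intervals, and an optional Mantel–Haenszel pooled OR.
* **Dynamics** — membrane-ruffle count and speed from kymographs, and
  mean marker intensity in a 3-µm leading-edge band of confocal
  z-series.
* **Gene screen** — two-fold-change / p ≤ 0.05 volcano screen of a
  curated gene list, with cross-dataset recurrence ranking.
* **Synthetic data** — generators for point patterns (Poisson, Thomas
  cluster, hardcore), rendered tissue images, z-series, kymographs,
  DCIS sections, contingency tables and expression matrices, all with
  planted ground truth, so the entire pipeline is testable without the
  original imaging data.

## Worked example

```r
library(invadex)

# a dispersed synthetic tumor: Poisson cells at 0.04 cells/um^2
cfg <- sim_config(seed = 11, window = c(0, 0, 500, 500), pixel_size = 0.5)
gp  <- generate_point_pattern(cfg, "poisson", intensity = 0.04)
lii_from_pattern(gp$pattern)
#> LII = 2.50 um (low bin); 9750 of 9940 cells after border correction
```

At this density the mean NND matches the Poisson closed form
1/(2√0.04) = 2.5 µm; 190 border cells were excluded by the NND-zone
rule. (A *tumor* at 2.5 µm LII is in the low bin; the 7–9 µm clinical
bins correspond to much sparser cell densities.)

```r
# one study of a lymph-node meta-analysis: exposed 20/10, unexposed 5/40
tb <- contingency_2x2(20, 10, 5, 40, study_id = "study_1")
odds_ratio(tb)        # 16
fisher_exact_p(tb)    # 8.0e-07
exact_ci(tb)          # 4.267  65.62   (exact 95% CI)

# DCIS index: 10 intact structures, cellular 1 mm^2 of tumor 2 mm^2
dcis_index(dcis_section(10, tumor_area = 2, cellular_area = 1))
#> DCIS index 2.5 per mm^2 (cellular coefficient 0.500)

# membrane ruffles from a synthetic kymograph (3 traces at 2 um/min)
k <- generate_kymograph(sim_config(3, c(0, 0, 20, 20), pixel_size = 0.2),
                        n_ruffles = 3, speed = 2)
detect_ruffles(k$kymo)
#> 3 ruffle trace(s) over 45.0 min; mean speed 2.00 um/min
```

The odds ratio 16 with p ≈ 10⁻⁶ and a CI excluding 1 says this
(synthetic) study found strongly elevated dissemination odds under
exposure; the kymograph readout recovers the planted ruffle count and
speed.

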