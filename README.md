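# ccfv — choriocapillaris flow-void analysis around geographic atrophy

`ccfv` is an R package for quantifying choriocapillaris (CC) flow
impairment around geographic atrophy (GA) on en-face OCT angiography, and
for relating that impairment to the lesion's growth rate. It is aimed at
retinal imaging groups who have co-registered en-face CC image pairs
(structural + angiogram), manual GA masks at two visits, and a fovea
location, and who want the standard flow-void / growth-rate analysis chain
as tested, scriptable code rather than an ImageJ click-path.

## What it computes

Per eye, from the baseline angiogram and the two GA masks:

* shadow **compensation**: `flow ⊙ G(1 − structure)` with a 3 × 3 Gaussian
  `G` — drusen shadow darkens the structural channel, so the inverted,
  smoothed structure boosts the attenuated flow signal;
* **binarization** into flow voids by the Phansalkar local threshold
  `t = m (1 + p e^{−q m} + k (s/R − 1))` over a circular window
  (radius 15 px ≈ 88 µm at 1024 px / 6 mm; constants k = 0.25, R = 0.5,
  p = 2, q = 10);
* **ring regions** from the exact Euclidean distance transform of the
  lesion: para-atrophy (0–500 µm from the edge) and peri-atrophy
  (500–1000 µm), plus everything outside the lesion;
* **flow-void percentages** FV_OUT, FV_500, FV_1000 and their difference
  **ΔFV = FV_500 − FV_1000**;
* the square-root-transformed yearly growth rate
  **yGR = (√GA_II − √GA_I)/FU** (mm/yr), with border-touching lesions
  flagged for exclusion;
* the **fovea distance** (mean over foci of centroid-to-fovea distance).

Cohort-level: Pearson correlations of yGR with each flow-void measure,
two-grader ICC(2,1) with F-based confidence intervals, and a univariable
GEE screen (Gaussian, identity link, exchangeable working correlation,
robust SEs, patients as clusters) followed by a multivariable GEE over the
screened-in covariates.

A synthetic cohort generator (`synthetic_config()`, `generate_cohort()`)
produces image pairs, masks and truth tables with known void fractions and
growth speeds, so the whole chain is validated by recovery tests.

## Worked example

```r
library(ccfv)

cfg <- synthetic_config(n_patients = 6, grid_px = 256, seed = 7)
coh <- generate_cohort(cfg)

eye <- coh$eyes[[1]]
rec <- analyze_eye(eye$flow, eye$structure, eye$mask_t0, eye$mask_t1,
                   eye$fu_years, eye_id = eye$eye_id,
                   patient_id = eye$patient_id, age = eye$age,
                   bin_params = binarization_params(radius_px = 4))
round(rec[, c("GA_I", "GA_II", "FU", "yGR", "FV_OUT", "FV_500",
              "FV_1000", "dFV", "fovea_dist")], 3)
#>    GA_I GA_II    FU   yGR FV_OUT FV_500 FV_1000   dFV fovea_dist
#> 1 2.791 3.853 1.092 0.268 38.815 43.397  40.372 3.025      1.157
```

This eye's lesion grew from 2.79 to 3.85 mm² over 1.09 years, a yGR of
0.27 mm/yr; flow voids cover 43.4% of the para-atrophy ring against 40.4%
of the peri-atrophy ring, so the marginal excess ΔFV is 3.0 percentage
points. (The binarization radius is 4 px because this example runs on a
256-px grid: it keeps the physical window at ≈ 88 µm.)

Cohort statistics over all generated eyes:

```r
res <- do.call(rbind, lapply(coh$eyes, function(e)
  analyze_eye(e$flow, e$structure, e$mask_t0, e$mask_t1, e$fu_years,
              eye_id = e$eye_id, patient_id = e$patient_id, age = e$age,
              bin_params = binarization_params(radius_px = 4))))
st <- cohort_stats(res)
st$correlations
#>   measure         r           p n
#> 1  FV_OUT 0.8937955 0.006662595 7
#> 2  FV_500 0.8499650 0.015420728 7
#> 3 FV_1000 0.8486503 0.015749060 7
#> 4     dFV 0.8056406 0.028719893 7
```

With the generator's default growth coupling, eyes with more peri-lesional
flow-void excess grow faster, and the correlations recover that. The GEE
screen and multivariable model are in `st$gee`; `cohort_stats()` also
writes `table1.csv` and `correlations.csv` when given an `output_dir`.

Disk-based runs mirror the in-memory API: `simulate_cohort_dir()` writes
TIFF/PNG/CSV bundles, `analyze_cohort_dir()` reads them back, writes
`results.csv`, a JSON run manifest and optional QC overlays. A thin CLI
over the same functions ships at `inst/scripts/ccfv.R`
(`simulate` / `analyze` / `stats` / `qc` subcommands, YAML config).

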