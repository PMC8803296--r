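# sprct

Stopping-power-ratio (SPR) prediction and range evaluation for ion-beam
therapy CT workflows.

## What this is for

Proton, helium and carbon-ion treatment planning converts a CT image into a
per-voxel map of the stopping-power ratio relative to water; the map's
accuracy decides where the Bragg peak lands (roughly, 1% SPR error ≈ 1 mm
range error per 10 cm depth). Two imaging routes compete:

* **SECT** — single-energy CT plus a stoichiometrically calibrated
  piecewise-linear Hounsfield look-up table (HLUT),
* **DLCT** — dual-layer spectral CT, whose electron-density (ρe) and
  effective-atomic-number (Z_eff) images feed the Bethe formula directly:

  SPR = ρe · L(I) / L(I_w),  L(I) = ln(2 m_e c² β² / (I(1−β²))) − β²,

  evaluated at a fixed 100 MeV with I_w = 78.73 eV, the voxel I-value
  coming from a water-anchored piecewise-log-linear Z_eff→I model
  (Z_eff uses the electron-fraction-weighted power mean with exponent
  2.94).

`sprct` implements both chains, the two-parameter stoichiometric CT-number
model and HLUT machinery, a synthetic labeled head phantom with a scanner
error model, per-ray water-equivalent path length (WEPL) transport with
analytical pristine/spread-out Bragg peaks, distal R90/R80 range-shift
extraction, and the evaluation statistics used to compare modalities: ROI
SPR tables with paired t-tests, range-shift percentile summaries and
intra/interpatient variabilities, local 3D gamma analysis (1%/1 mm, 5%
cutoff) and DVH metrics (Dmean, D0.03cc, D99).

It is a research tool for medical physicists studying CT-based range
uncertainty; it is not a treatment-planning system.

## Worked example

A two-patient proton study in which the simulated DLCT scanner carries a
+1% electron-density bias against a self-consistent SECT chain:

```r
library(sprct)

ean_from_composition(water_composition())   # 7.4167
ground_truth_spr(reference_tissues()$brain) # 1.0361

res <- run_study(study_config(n_patients = 2, ions = "proton",
                              scanner = scanner_model(ed_bias = 0.01),
                              evaluate_dose = FALSE, seed = 42))
res$roi_cohort
#>            roi n_patients median_delta_pct mean_delta_pct sem_delta_pct
#> 1        brain          2                1              1             0
#> 2 cranial_bone          2                1              1             0
#> ...
res$summary_by_plan[, c("group", "n", "mean", "sd", "p50", "p100")]
#>   group  n    mean       sd     p50    p100
#> 1     A 30 0.01040 9.59e-05 0.01039 0.01059
#> 2     B 20 0.00968 8.29e-05 0.00966 0.00987
#> 3     C 20 0.01043 9.55e-05 0.01043 0.01065
#> 4     D 20 0.01052 2.99e-05 0.01052 0.01057
res$variability
#> intrapatient 0.033%, interpatient 0.001%
```

Reading the output: a +1% ED bias shifts every ROI's mean SPR by +1%
(`delta_pct`), and the per-profile relative R90 range differences
(`mean`, as fractions) land at ≈1% across all four plan archetypes —
the uniform-scaling range law in action. On this homogeneous synthetic
cohort the spread between patients is tiny, unlike in real anatomy; see
the methods vignette (`vignettes/spr-methods.Rmd`) for what the phantom
does and does not emulate.

A full study (6 patients × 4 plan archetypes × 3 ions, with dose volumes,
gamma and DVH evaluation) runs in minutes:

```r
res <- run_study(study_config(seed = 1))
write_study_outputs(res, "study_out")   # table1_roi_spr.csv, table2_..., manifest.json
```

or from a shell: `Rscript inst/scripts/run_study.R --config study.yaml --out study_out`.

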