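---
title: "Stopping-power-ratio prediction from spectral and single-energy CT: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stopping-power-ratio prediction from spectral and single-energy CT: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ion-beam therapy (protons, helium, carbon ions) places its dose at a depth
controlled by the stopping-power ratio relative to water (SPR) of the tissue
along each beam. Treatment planning therefore needs a per-voxel SPR map
derived from CT imaging, and the accuracy of that map translates directly
into range accuracy: a systematic SPR error of 1% moves the distal dose edge
by about 1 mm per 10 cm of range.

Two imaging routes compete:

* **Single-energy CT (SECT)**: the clinical standard. The scanner produces
  Hounsfield numbers; a piecewise-linear Hounsfield look-up table (HLUT),
  calibrated stoichiometrically against tissue surrogates, converts them to
  SPR.
* **Dual-layer spectral CT (DLCT)**: a two-layer detector acquires low- and
  high-energy data simultaneously, yielding relative electron density (ED,
  $\rho_e$) and effective atomic number (EAN, $Z_{\mathrm{eff}}$) images.
  SPR then follows from physics rather than a lookup: the Bethe formula.

`sprct` implements both chains end to end, a synthetic head phantom and
scanner simulator to drive them, a simplified per-ray transport model for
range analysis, and the evaluation statistics (ROI SPR differences, R90/R80
range shifts, local 3D gamma, DVH metrics) used to compare them.

## The DLCT chain

SPR is computed voxel-wise at a fixed "effective" kinetic energy of 100 MeV
with proton kinematics:

$$\mathrm{SPR} = \rho_e \,\frac{L(I)}{L(I_w)},\qquad
L(I) = \ln\!\frac{2 m_e c^2 \beta^2}{I\,(1-\beta^2)} - \beta^2,\qquad
\beta^2 = 1 - \left(1 + \frac{E}{Mc^2}\right)^{-2},$$

with the mean excitation energy of water fixed at $I_w = 78.73$ eV and
higher-order Bethe corrections neglected. The energy dependence of the
ratio is tiny across the therapeutic window — the package's tests bound the
80 vs 200 MeV difference below 0.2% for soft tissues — which is what makes
a single fixed-energy SPR map usable for all three ion species. For bone
the same difference reaches about 0.5% (the spread in $\ln I$ is larger);
this is an intrinsic property of the Bethe ratio, documented here rather
than hidden.

The voxel I-value comes from a parametric EAN-to-I map. EAN itself is the
electron-fraction-weighted power mean
$Z_{\mathrm{eff}} = (\sum_i \lambda_i Z_i^{n})^{1/n}$ with exponent
$n = 2.94$, matching the convention of the scanner vendor's spectral
output.

### The EAN-to-I model and the water anchor

The exact vendor parametrization is proprietary, so the package fits its
own: a continuous piecewise-linear curve in $(Z_{\mathrm{eff}}, \ln I)$,
estimated by least squares on a hat-function basis over configurable knots
and constrained through water, $(Z_{\mathrm{eff},w}, \ln 78.73)$.

Two numerical choices matter here:

* **Effective I-values as fit targets.** Bragg additivity over elemental
  I-values gives water about 69 eV, not the adopted 78.73 eV. Fitting raw
  Bragg values under a 78.73-eV water anchor would inject a systematic
  SPR offset of roughly 1.7% for every tissue. The fit therefore targets
  *effective* I-values: for each reference tissue, the I that makes the
  100-MeV Bethe chain reproduce the Bragg-additivity ground-truth SPR
  exactly. This is the usual renormalization that reconciles elemental
  additivity with a measured water I-value, and it makes the water identity
  exact by construction.
* **Knot placement.** Default interior knots sit at EAN 8, 9.5, 11 and
  12.5. One boundary near the classic soft-tissue/bone split would be the
  minimal model, but $\ln I$ versus EAN is visibly curved along the bone
  branch; with a single bone segment the leave-one-out error on the
  embedded tissue table reaches 8–11 eV, while the default knots keep it
  below 5 eV and the chain SPR residual below 0.35% (soft tissue) and
  0.25% (bone). A single knot at 8.5 remains available via the `knots`
  argument for the traditional two-segment form.

Observed EAN is clipped to [1, 16] before lookup, and voxels with ED below
0.05 are floored to SPR 0.001: the stopping-number ratio is ill-conditioned
for near-vacuum voxels, and air cavities are better served by a fixed floor.

## The SECT chain

Theoretical CT numbers follow the two-parameter stoichiometric form

$$\frac{\mu}{\mu_w} = \frac{\rho_e\,(k_1 \tilde Z_1^{3.62} +
k_2 \tilde Z_2^{1.86} + 1)}{(k_1 \tilde Z_{1,w}^{3.62} +
k_2 \tilde Z_{2,w}^{1.86} + 1)},\qquad \mathrm{HU} = 1000(\mu/\mu_w - 1),$$

with $\tilde Z_j$ electron-fraction-weighted power means of Z. The
exponents 3.62 (photoelectric) and 1.86 (coherent scatter) are the
customary literature values and are configurable. $(k_1, k_2)$ are fitted
to insert readings by non-negative least squares after rearranging the
model into a form linear in the two parameters, so noise-free readings are
inverted exactly. The package's "scanner truth" uses
$k_1 = 3.46\times10^{-5}$, $k_2 = 5\times10^{-4}$, chosen once to give
conventional 120 kVp-like values (adipose near −72 HU, cortical bone near
1550 HU, air near −999 HU).

Because no surrogate measurement data are shipped, the calibration inserts
are synthetic: reference tissues plus density-graded lung and
soft-tissue/cortical-bone mixtures spanning the clinical HU range
(`synthetic_inserts()`). Calibration is still a genuine inverse problem —
readings are generated by the truth parameters (optionally with noise) and
the fit must recover them.

The HLUT is built from the (predicted HU, ground-truth SPR) points of
reference tissues. The default construction uses ten segments with fixed
HU knots at (−1000, −120, −80, −30, 0, 50, 100, 300, 800, 1600, 3071),
segment-wise least squares, vertex averaging between adjacent segments,
neighbor interpolation for under-populated segments, an air anchor at
(−1000, 0.001), a forced water vertex (0 HU, SPR 1) and a running-maximum
monotonicity guard. A one-to-one identity curve (`hlut_identity()`)
reproduces the workaround by which SPR images can be smuggled through a
planning system's CT-conversion slot.

## The synthetic head phantom and scanner model

The phantom is a concentric-ellipsoid head: soft-tissue scalp, cranial
bone shell, brain, skull-base bone slab, two eyes, two CSF-filled lateral
ventricles and a nasal air cavity, rasterized by highest-priority-wins at
voxel centers on a 2 mm grid by default. Compositions are embedded
ICRU-44/ICRP-style adult reference tissues (the table ships as plain CSV).
Ground-truth ED/EAN/SPR volumes follow per voxel from the assigned
composition; air is a material, not vacuum, so air-cavity discrepancies can
be studied.

Only radiological-depth structure matters for per-ray range analysis, so
no image-derived anatomy is used; per-patient variability is emulated by
seeded ±3% anatomical scale jitter. The scanner model applies
multiplicative per-tissue or global biases plus seeded Gaussian noise to
the truth volumes (DLCT: ED/EAN; SECT: HU). The bias magnitudes are the
experiment's control knob: imposing a percent-level ED bias reproduces
percent-level inter-modality SPR discrepancies of the kind observed
clinically. What the generator does *not* emulate: reconstruction texture
and correlated noise, beam hardening and metal artifacts, partial-volume
mixtures at interfaces, or real anatomical heterogeneity. Passing tests on
this phantom therefore validate the analysis chain's correctness and
sensitivity, not clinical SPR accuracy.

## Beam and range model

Transport is strictly per-ray: water-equivalent path length (WEPL) is the
line integral of SPR, sampled at the midpoint of fixed steps (default half
the voxel spacing) with trilinear interpolation, and the dose along a ray
is the spread-out-Bragg-peak (SOBP) curve evaluated at the WEPL of each
sample. No lateral scatter, penumbra or nuclear interactions are modeled;
dose volumes assign each in-field voxel the dose of its nearest ray.
Biological modeling is reduced to a fixed RBE scalar (1.1 for protons, 1.0
otherwise).

Pristine peaks are analytical: a rising entrance plateau times a Gaussian
peak times an error-function distal fall-off of width
$\sigma = c_{\mathrm{ion}} R_0^{0.935}$, shifted so the distal
80%-of-maximum depth equals $R_0$ exactly. The constants
$c_p = 0.022$, $c_{\mathrm{He}} = 0.012$, $c_C = 0.007$ are model
parameters, not measured values; they represent the *total* fall-off width
(straggling plus beam energy spread) and preserve the physical sharpness
ordering proton > helium > carbon. Straggling-only constants half this
size would make a 12-peak SOBP's ±2% plateau flatness unattainable (the
superposed error-function edges form a staircase that no non-negative
weighting can flatten), which is why the totals are used.

SOBP weights solve a non-negative least-squares flatness problem on
[d_prox, d_dist]; component ranges extend ~2.2σ beyond d_dist so the
distal fall-off begins after the flat interval. The default component
count targets a spacing of 1.2σ (at least 12), so sharper ions get more
energy layers. R90/R80 are the most distal crossings of 90%/80% of the
*prescribed* plateau dose, located by linear interpolation; range depths in
shift records are measured from each ray's skin entry (taken from the
planning map) so that surrounding air does not dilute relative shifts.
Relative shifts follow the convention (SECT − DLCT)/DLCT; absolute shifts
are |SECT − DLCT|.

## Evaluation layer

* **ROI SPR statistics**: circular per-slice ROIs seeded automatically at
  structure centroids (brain 100 mm² × 10 slices, eyes 100 × 5,
  ventricles 50 × 5, cranial bone 50 × 10, skull base 25 × 10); per-slice
  relative differences of slice means, then per-patient mean ± SD and
  cohort median/mean ± SEM. Paired two-sided t-tests with a 95% CI; a
  zero-variance degenerate case is flagged rather than erroring.
* **Summaries**: percentiles interpolate order statistics (type 7), SD uses
  n−1, box-plot whiskers use the 1.5 × IQR rule. Intrapatient variability
  is the mean of per-patient SDs; interpatient the SD of per-patient means.
* **3D gamma**: local normalization at 1%/1 mm with a 5% low-dose cutoff by
  default. Candidates live on a 0.1·DTA lattice within a 3·DTA sphere,
  visited by increasing radius with per-voxel early exit (once the distance
  term alone exceeds the running minimum, no further candidate can
  improve). The test suite checks agreement with an exhaustive fine-lattice
  search; note local gamma is not symmetric under swapping reference and
  evaluated distributions.
* **DVH**: Dmean is the plain voxel mean; D0.03cc the minimum over the
  hottest ⌈0.03 cc / voxel volume⌉ voxels (falling back, flagged, to the
  maximum for smaller structures); D99 the dose received by at least 99%
  of the volume via interpolated order statistics. OAR flags use a strict
  \> 0.5 Gy threshold on |ΔDmean| and |ΔD0.03cc|; PTV coverage reports the
  signed D99(SECT) − D99(DLCT).

## The cohort pipeline

`run_study()` wires everything together: per patient, phantom → simulated
acquisitions → both SPR maps (calibrated once per scanner) → per-plan
beams with SOBP intervals fixed on the SECT map and dose recalculated,
without reoptimization, on the DLCT map → five equidistant profiles per
beam → records, gamma, DVH tables. Four plan archetypes mimic realistic
head cases: A (brain target, three beams), B (small skull-base target, two
nearly opposing beams through heavy bone), C (target as A, two beams 60°
apart), D (central target, two nearly opposing fields). Archetype sizes
and OAR stand-ins (brainstem- and chiasm-like ellipsoids) are config
defaults, stated as assumptions.

One design choice deserves emphasis: by default the study uses
*interpolating* calibrations — EAN-to-I knots at every reference-tissue
EAN and HLUT vertices at every reference-tissue (HU, SPR) point, with air
mapped to the same 0.001 floor on both sides. On a phantom made of
finitely many materials this renders both chains exact, so a scanner with
zero modality discrepancy produces *identical* SPR maps and the null study
yields exactly zero range shifts, 100% gamma and zero flags. That isolates
the quantity under study (the imposed modality discrepancy) from
calibration residuals, which are characterized separately with the fitted
calibrations (`calibration = "fitted"` and the chain-residual tests). The
default problem size — 6 patients × 4 plans × 3 ions on a 2 mm grid — was
chosen so a full null study with dose evaluation completes in minutes on a
single core.

## Known limitations

* The phantom's homogeneity makes per-ROI SPR differences essentially
  deterministic given the imposed bias; cohort SEMs are therefore much
  smaller than clinical ones.
* No lateral transport: gamma comparisons exercise distal-edge geometry,
  not penumbra differences.
* The EAN-to-I and HLUT models are methodologically faithful but not
  numerically identical to any clinical facility's curves; absolute
  patient-study numbers are out of reach by design, and the package's
  claims are property-based (identities, oracle agreement, scaling laws,
  ordering relations).
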