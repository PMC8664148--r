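---
title: "Methods: SBRT lung plan metrics, deviation classification, and algorithm-adapted guidelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SBRT lung plan metrics, deviation classification, and algorithm-adapted guidelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbrtdose)
```

## The problem

Stereotactic body radiotherapy (SBRT) for lung tumours delivers few, very
large dose fractions through low-density lung tissue. Plan quality is judged
against RTOG/NRG protocol criteria: target coverage (V100%, D95%, V90%),
hotspot control (V105%, Rx/Dmax), conformality (CI), and dose falloff (R50
and D2cm). These criteria were established when convolution-type dose
engines (such as the analytic anisotropic algorithm, AAA) were standard.
Linear Boltzmann transport solvers (Acuros XB, AXB) model the electronic
disequilibrium at lung/tissue interfaces more faithfully and systematically
report lower target coverage for the same monitor units. A plan that meets
the protocol limits under one engine therefore does not deliver the same
dose as a plan meeting them under the other, and the limits themselves need
rescaling before they can be applied to AXB-calculated plans.

This package implements the full evaluation chain: metric computation from
3D dose grids and structure masks, deviation classification with
volume-interpolated thresholds, renormalization to a coverage target,
cohort statistics, and the derivation of algorithm-adapted guideline tables
by cohort-mean ratio scaling. A synthetic paired-plan generator stands in
for clinical data so the entire pipeline runs and is tested without any
protected health information.

## Metric definitions and conventions

All percent-dose quantities are relative to the prescription `Rx`. On a
structure's voxel dose multiset (no histogram binning — bin width would be
a hidden parameter):

* `Dx%` — largest voxel dose `d` such that at least x% of the structure
  volume receives `>= d`. Voxel-exact, never interpolated between voxels.
* `Vd` — percent of structure volume with dose `>= d` (inclusive).
* V105% — volume **outside** the PTV with dose strictly above 105% of Rx,
  as a percent of PTV volume. The strict inequality follows the protocol's
  ">105%" wording; coverage metrics use the inclusive ">=".
* Dmin — near-minimum dose: the highest dose received by all but the
  coldest 0.03 cc. Defined so that a cold volume of 0 reduces to the plain
  minimum.
* CI — prescription isodose volume over PTV volume; R50 — half-prescription
  isodose volume over PTV volume. Both isodose volumes are evaluated over
  the whole grid (or a body mask when supplied), not only near the target,
  so `R50 >= CI` always.
* D2cm — maximum dose (in % of Rx) at any voxel whose centre lies strictly
  more than 20 mm from the nearest PTV voxel centre. The distance field is
  an exact Euclidean distance transform (separable lower-envelope
  algorithm) honouring anisotropic spacing; no sub-voxel surface model is
  introduced because the protocols define none.
* Island-type target: minimum PTV-to-chest-wall distance of at least 10 mm,
  inclusive at the boundary.

Volumes are voxel counts times the voxel volume, with voxel centres as the
geometric reference (position of voxel (i,j,k) is
`origin + (index - 1) * spacing`). Grids are axis-aligned; oblique
orientations are rejected at read time rather than resampled.

## Deviation classification

For CI, R50 and D2cm the protocol defines, per PTV volume, a "none" limit
and a minor-deviation band: below the none limit is no deviation, the
closed band `[none, minor_upper]` is a minor deviation, above it is major.
Thresholds at volumes between the tabulated rows are linearly interpolated
in PTV volume and clamped to the first/last row outside 1.8–163 cc. The
volume-independent criteria (V100%, V90%, V105%, Rx/Dmax) are pass/fail
only.

The normalised metrics divide the measurement by the interpolated
none/minor boundary:

$$D'_{2cm} = \frac{D_{2cm}^{meas}}{D_{2cm}^{minor}}, \qquad
  R50' = \frac{R50^{meas}}{R50^{minor}}$$

so a value below 1.0 meets the guideline at any target size (a 48% D2cm
against a 50% boundary gives 0.96). The denominator is the dose level at
which a minor deviation *begins*, which the worked example fixes
unambiguously.

One source-data subtlety: the published summary of the volume-specific
table rounds the R50 "none" column to integers (e.g. "<5" at 22 cc), while
the same publication's derivation table carries the protocol's exact
falloff limits (4.7/4.5/4.3/4.0 at 13.2/22/34/50 cc) — only those values
reproduce the derived limits (4.7 × 0.892/0.899 = 4.66). `rtog_table1()`
therefore uses the exact values at those four volumes and the printed
values elsewhere.

## Renormalization

Recalculating a plan with a different dose engine at fixed MU changes the
absolute dose; clinically the plan is then renormalized so that 95% of the
PTV again receives the prescription. `renormalize()` implements this as a
pure global scaling: `scale = Rx / D95`, applied to every dose voxel and to
the MU (beam weights are untouched, so the relative spatial distribution is
unchanged). The voxel-exact DVH makes the post-renormalization D95 land on
Rx exactly, and the MU ratio equals the dose scale by construction.

## Guideline derivation

For each metric the cohort-mean ratio between the recalculated and original
arms is computed; the current limits times these ratios give the proposed
limits. D2cm and R50 thresholds are scaled by the ratios of the normalised
D'2cm and R50' means (the only forms comparable across target sizes); CI by
the raw CI ratio; the coverage recommendations (D95%, V100%) are the
recalculated-arm means themselves. Per-column rounding is explicit
configuration, chosen to match how such limits are conventionally printed:
D2cm to the nearest integer percent, R50 truncated (not rounded) at two
decimals, CI to two decimals, percent limits to one decimal. With these
rules the derivation reproduces the published proposed tables from the
published cohort means, with one exception: the published CI major-limit of
1.41 is not reachable from the printed means (1.5 × 1.07/1.15 = 1.3957),
so the derivation emits 1.40 and the discrepancy is documented rather than
hard-coded around.

The volume-specific output is restricted to 13.2–50 cc by default — the
volume range the reference cohort supports — with `full_range = TRUE`
available behind an explicit warning. A derived coverage recommendation
below 100% implies a prescription reduction if equal delivered coverage is
wanted: `scaled_prescription(60, 98.2)` gives 58.92 Gy.

## Cohort statistics

Arm comparisons use the classical two-sided paired t-test on within-pair
differences (df = n − 1), implemented in closed form and cross-checked
against `stats::t.test` in the test suite. Zero-variance differences are
flagged as degenerate instead of reporting an unstable p-value. No
multiple-testing correction is applied, matching the reference analysis.
The target-size effect splits the cohort at 20 cc and compares
plan-to-recalculated relative differences `(M_rec − M_plan)/M_plan`
between strata with an unpaired Welch t-test; the reference analysis names
no test for this comparison, so the choice is ours and is stated here.

## The synthetic cohort generator

The generator is phenomenological: it reproduces the *metric-level*
structure of paired plans, not particle transport. Each patient gets:

* a spherical PTV, volume drawn log-normally (median ~19 cc, truncated to
  7.58–74.06 cc, cohort mean ≈ 21 cc); 13 of 30 patients are island-type
  (placed ≥ 14 mm from a chest-wall slab), the rest abut it;
* a dose field radially symmetric about a centre *offset* from the PTV
  centre: interior dose rising from Rx at the prescription isodose to a
  hotspot (Rx/Dmax ~ N(0.83, 0.03) truncated to [0.62, 0.88]), an
  exponential-type falloff anchored so that the drawn per-patient R50'
  (~N(0.899, 0.09)) is hit, and a small near-target hot lobe supplying the
  V105 volume. The offset magnitude is solved from sphere-overlap geometry
  so that the prescription isodose (CI ~ N(1.15, 0.05)) covers exactly 95%
  of the PTV; the dose is then normalized so D95 = Rx voxel-exactly;
* monitor units ~N(2301, 250) for island and ~N(1973, 250) for non-island
  patients, giving a cohort mean near 2115.

The algorithm shift multiplies the dose by a per-patient factor drawn
around the configured D95 ratio (0.9703 island / 0.9911 non-island, sd
0.02 — the mixture reproduces the overall 0.9821), faded out with distance
beyond the PTV over 5 mm (the build-up deficit is a near-target effect;
this is what keeps R50 nearly unchanged while coverage drops), deepens
doses below the prescription slightly (cold rim, 1%), boosts the hotspot
(2.9%), and trims far-field dose by 0.2%. A deterministic anchor
correction keeps the realized per-plan D95 ratio equal to the drawn ratio
despite the dose-level gates. MU are left unchanged, as recalculation
reuses the original MU.

The interior dose gradient at the prescription isodose (exponent 3.7 of
the radial profile) sets how much V100 falls per percent of D95 drop; the
calibration in `tools/calibrate_shift.R` fixed it, once, so that a
30-patient cohort lands near the reference means (V100 ≈ 91.4% after
recalculation, CI ratio ≈ 0.93). All defaults were frozen after that
single calibration pass and are not adjusted per seed.

What the generator does **not** emulate: beam entrance/exit dose. The
falloff is monotone in distance, so the dose beyond 2 cm is far lower than
in clinical arc plans and the synthetic D'2cm means sit near 0.6 rather
than the clinical ~1.0. Synthetic deviation counts are therefore not
comparable to the clinical tables (which the reference data alone
determine); tests assert count bookkeeping and the direction of
renormalization effects (R50 deviations can only grow when dose is scaled
up), not clinical count values. Likewise tissue heterogeneity, motion and
plan-specific aperture shapes are out of scope.

## Numerical choices and degenerate inputs

* Problem sizes: the default grid is 56 × 48 × 48 voxels at 2.5 mm —
  large enough that the largest PTV (74 cc) keeps its half-prescription
  isodose inside the grid — and test cohorts use n = 30 patients over
  three seeds, the reference study size.
* DVH quantiles, near-minimum and isodose volumes are exact multiset
  operations; property tests compare them to independent sort/scan
  oracles on hundreds of random grids, and the distance transform to
  all-pairs brute force.
* Rounding of derived limits uses round-half-away-from-zero (base R's
  banker's rounding would corrupt printed-table reproduction) and
  truncation for the R50 columns.
* Empty masks: volume 0 with a warning where a structure is optional; an
  error wherever a nonempty PTV is required. A missing chest-wall mask
  makes the island flag `NA` rather than guessing. Renormalization
  refuses a zero dose at the coverage target; D2cm errors when no voxel
  lies beyond the margin (grid too small).
* Determinism: every stochastic step derives its seed from the cohort
  seed and patient index; the same (seed, index) pair yields bit-identical
  plans, and generators save/restore the global RNG state.

## Limitations

The synthetic cohort shares its dispersion parameters with published
ranges where available (MU change spanning roughly −2% to +7%) but the
paper reports few spreads, so the standard deviations are configuration,
not claims. The derivation reproduces published limits exactly only under
the stated rounding rules, which were reverse-engineered and are logged
with each derivation. Classification follows the printed boundary
conventions (strict "none" limit, closed minor band); a TPS that
interpolates DVHs sub-voxel may disagree at exact boundaries.
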