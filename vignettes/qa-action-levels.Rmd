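---
title: "Action levels for independent secondary dose calculation QA: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Action levels for independent secondary dose calculation QA: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doseqa)
```

## The problem

Patient-specific quality assurance (PSQA) by independent secondary dose
calculation (ISDC) compares a treatment planning system's (TPS) 3D dose
distribution with an independent recomputation of the same plan. Two metrics
summarize the comparison: the **gamma pass rate** GPR(DD, DTA) — the
percentage of evaluated points whose gamma index is below 1 at a
dose-difference tolerance DD (% of the global maximum) and a
distance-to-agreement tolerance DTA (mm) — and the **relative difference in
mean target dose** ΔD (%), positive when the ISDC dose is higher.

The question this package operationalizes is not "is this plan good?" but
"which action level can a clinic afford?" An action level flags plans for
investigation; a stricter level is more sensitive but flags more false
positives and thus costs workload. Given a representative cohort, the package
derives the action level that produces a chosen plan failure rate
q ∈ {0.02, 0.05, 0.1, 0.2} by counting — taking percentiles of the cohort's
QA results — and compares that purely empirical route with the parametric
TG-218 action-interval formalism.

## The gamma engine

For each reference voxel above the low-dose threshold (default: 5% of the
reference maximum, excluded from numerator and denominator alike),

$$\gamma = \min_{r} \sqrt{\frac{|r - r_\mathrm{ref}|^2}{\mathrm{DTA}^2} +
  \frac{(D_\mathrm{eval}(r) - D_\mathrm{ref}(r_\mathrm{ref}))^2}
       {(\mathrm{DD} \cdot D_\mathrm{ref,max})^2}}.$$

Design choices, fixed once and documented:

* **Direction**: the TPS grid is the reference; gamma is evaluated at its
  voxel centers. The evaluated (ISDC) grid may live on a different
  axis-aligned geometry and is interrogated by trilinear interpolation.
* **Normalization** is global, by the reference maximum. Prescription-dose
  normalization is exposed (`norm_dose`) but not the default.
* **Strictness**: a point passes when γ < 1, strictly. A uniform +2% offset
  at (2%, 2 mm) therefore yields GPR = 0, not 100: γ = 1 exactly.
* **Search**: candidates are the evaluated voxel centers within the capped
  radius plus a sub-voxel lattice of step DTA/10, nearest first, with an
  early break as soon as the spatial term alone exceeds the running best.
  Values are capped at 2; the cap bounds runtime and is irrelevant to the
  pass rate.
* **Oracle**: `brute_force_gamma()` is a second, pure-R implementation —
  exhaustive over all evaluated voxel centers, no radius bound, no shared
  code with the engine. With interpolation disabled the engine must equal it
  voxel for voxel; with interpolation enabled it can only be lower (its
  candidate set contains the voxel centers). Both facts are asserted in the
  test suite on dozens of random grid pairs.

## Per-plan metrics and the cohort table

`evaluate_plan()` resamples the evaluated grid onto the reference geometry
once (trilinear; out-of-support voxels are zero-filled, flagged, and excluded
from gamma statistics), computes ΔD over the target mask, and the GPR at the
four study criteria (5,3), (3,3), (2,2), (2,1). Results travel as a plain
CSV with columns `plan_id, case_class, technique, delta_d, gpr_5_3, gpr_3_3,
gpr_2_2, gpr_2_1`, which every downstream stage consumes. Dose-volume
metrics beyond the mean target dose are deliberately out of scope.

## Percentile action levels

The q-quantile of the cohort's GPR values (linear-interpolation percentile,
R's type 7 — the convention is documented because the choice matters at
n = 100) is rounded to a multiple of 5 GPR points; the (1−q)-quantile of
|ΔD| is rounded to a multiple of 0.5 points. "Rounding to the next multiple"
is ambiguous, so the package implements two conventions: **nearest** (ties
toward the lenient side — lower for GPR, higher for |ΔD|; the default) and
**outward** (always lenient). A plan fails when GPR < threshold or
|ΔD| > threshold, strictly. The combined criterion fails a plan only when it
fails *both*, and `combined_table()` keeps the exact bookkeeping identity
`passed_both = 100 − failed_gamma − failed_dd + failed_both`.

## The TG-218 formalism

The action interval is `2A = β·√(σ² + (x̄ − T)²)` around the target value T
(100 for GPR, 0 for ΔD); levels are T ± A, one-sided for GPR. Under a
Gaussian model, β/2 maps to a failure rate q through the normal CDF —
one-sided `β/2 = z(1−q)`, two-sided `β/2 = z(1−q/2)` — and
`expected_fail_rate()` predicts the failure fraction at any threshold.

Two caveats the package makes explicit:

* The interval is symmetric about T, not about the cohort mean. When the
  systematic offset |x̄ − T| is comparable to σ, the empirical failure rate
  at T ± A no longer equals the nominal q (it deviates by many binomial
  standard errors at n = 10⁵), although the Gaussian *prediction* of the
  rate at that threshold remains accurate. The acceptance suite asserts
  both statements separately; only the zero-offset case reproduces q
  exactly.
* GPR is right-truncated at 100. Near the bound the distribution is heavily
  asymmetric and the Gaussian conversion is too lenient.
  `truncation_beta_correction()` quantifies this with a declared generative
  model: a latent Gaussian clipped at 100, moment-matched to the requested
  clipped mean/SD by root-finding on the closed-form censored moments. The
  correction factor is ≈ 1 far from the bound and grows as the mean
  approaches 100; its precise value depends on the case mix, so it is
  treated as qualitative (> 1), not as a constant to reproduce.

## The synthetic cohort generator

The study's 100 clinical plans cannot be shared, so the generator is a
first-class, tested component with two tiers.

**Voxel tier** (`make_reference_plan()` / `perturb_plan()`): a 64×64×64 grid
at 2.5 mm — the Monte-Carlo ISDC voxel size of the study — with a 60 Gy
prescription inside an ellipsoidal target (radii 30/25/20 mm) and
exponential falloff (12 mm length, a plausible penumbra-plus-scatter scale)
outside. The evaluated grid applies, in order: a rigid shift; a per-plan
systematic scale error s ~ N(μ_sys, σ_sys) with the analytic-ISDC flavor
(1.75, 2.41)% as default; a smooth multiplicative field (Gaussian-filtered
white noise, 1% amplitude, 15 mm correlation length — standing in for
spatially structured algorithm differences); and optional iid voxel noise
calibrated so the relative SD inside the ≥ 70%-of-maximum region matches the
configured value (the study specified < 0.5% there). Noise calibration is
exact by construction and verified empirically in the tests.

**Result tier** (`sample_result_cohort()`): draws the QA table directly —
20 case classes × 5 plans, ΔD per flavor from the published cohort
statistics (M3D 1.75 ± 2.41, SMCgen −0.17 ± 1.03, SMCcbm −0.11 ± 0.78), and
GPR per criterion from the clipped-Gaussian model with a latent draw shared
across criteria so the ordering GPR(5,3) ≥ GPR(3,3) ≥ GPR(2,2) ≥ GPR(2,1)
holds per plan. Per-criterion GPR means/SDs are **not** published as numbers
(only as box plots), so the defaults — e.g. 96 ± 2 and 98 ± 1.4 for the
custom-beam-model flavor's strict criteria, the range quoted in the study's
discussion — are config-exposed choices, asserted nowhere.

What a green test does *not* establish: the generator has no anatomy, no CT
density model, no beams or MLC, and a single smooth target; it reproduces
the statistical structure the action-level machinery assumes, not clinical
dose distributions. Inter-algorithm engine discrepancies (the study could
not compute all GPRs with one engine) are likewise out of reach: this
package has exactly one engine.

## Numerical choices and degenerate inputs

* Gamma cap 2.0; sub-voxel step DTA/10; search radius cap·DTA (beyond it the
  spatial term alone exceeds the cap).
* Percentile type 7; action-level rounding as above; degenerate |ΔD|
  cohorts floor the threshold at one granularity step (0.5).
* All-zero reference grids, empty masks, empty included-voxel sets, q
  outside (0, 1), β ≤ 0, infeasible clipped-moment matches, and tilted DICOM
  orientations raise typed errors rather than producing numbers.
* RTDOSE I/O quantizes dose by the `DoseGridScaling` factor (default maps
  the maximum to ~2·10⁹ integer units, i.e. ~10⁻⁷ Gy resolution); round-trip
  is exact to stored precision and bit-identical once values are multiples
  of the scaling.
* Reproducibility: every stochastic operation takes a seed; cohort
  simulations derive one stream per plan from the master seed, so results
  do not depend on evaluation order.

## Known limitations

* One gamma engine, axis-aligned grids only, no local-normalization default,
  no 2D film/array gamma, no GPU path.
* No RTSTRUCT rasterization: masks are supplied or generated.
* The DICOM codec covers the explicit-VR little-endian RTDOSE subset the
  package writes — it is not a general DICOM reader.
* Printed-table reproduction is limited by the source's own rounding: two
  conversion-table entries (1.65 and 0.0014) are conventional prints of
  1.6449 and 0.00135; the package reproduces the arithmetic, and its tests
  say so explicitly.
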