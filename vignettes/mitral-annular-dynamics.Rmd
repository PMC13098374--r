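---
title: "Quantifying mitral annular dynamics and regurgitation from cardiac CT landmarks"
author: "mitralCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitral annular dynamics and regurgitation from cardiac CT landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitralCT)
```

## The measurement problem

In dogs with myxomatous mitral valve disease (MMVD), the mitral annulus (MA)
loses its normal pattern of systolic contraction and may instead expand
during systole, widening the regurgitant orifice. ECG-gated cardiac CT lets
an analyst place an ordered ring of 16 markers around the annulus at several
reconstructed cardiac phases; from those landmarks one can quantify annular
geometry through the cycle, and from biventricular volumetry one can
quantify mitral regurgitation (MR). `mitralCT` implements that analysis
chain: saddle-ring reconstruction and the annular metric panel, volumetric
MR quantification, arterial load indices, allometric body-size indexing,
and normality-gated paired pre/post-treatment statistics. Because per-dog
raw data from such studies are generally not deposited, the package also
ships a synthetic cohort generator with known ground truth, used to verify
the pipeline end to end (effect-size recovery, CI coverage, type-I error).

## Annulus model and the metric panel

Marker placement is an upstream manual step; the package takes the 16
ordered 3D markers (mm, device frame) with two flagged fibrous trigones as
input (`AnnulusLandmarkSet`). The reconstruction (`resampleRing()`) is:

1. **Curve model.** A closed periodic cubic interpolating spline through
   the 16 markers under chord-length parametrisation, resampled at `M = 512`
   approximately arc-length-uniform points. No curve model is canonical for
   the annulus; a periodic interpolating spline is the simplest smooth
   closed curve through ordered landmarks, and reconstruction error against
   analytic test rings is well below the 1% tolerance used throughout.
2. **Projection plane.** The total-least-squares plane of the resampled
   curve. "Projected area" presupposes a plane; the orthogonal-regression
   plane is the standard choice. The normal is oriented toward the left
   atrium using the declared marker winding (counter-clockwise from the
   atrial view), which fixes the sign of point elevations.
3. **Portions.** The trigones split the ring into two arcs; the shorter arc
   is labelled aortic (the trigones flank the aortomitral continuity), the
   longer parietal.

The metric panel:

* **MAA** (mm²): shoelace area of the curve projected onto the best-fit
  plane.
* **APD** (mm): the aortic and parietal horns are the maximal-elevation
  points of their portions; APD is the in-plane distance between their
  projections. For nearly flat rings (maximal elevation < 0.05 mm) horn
  identification by elevation is unstable, so the horns fall back to the
  intersections of the projected curve with the axis through the projected
  centroid and the trigone-chord midpoint; for flat symmetric rings both
  constructions coincide.
* **ICD** (mm): maximal caliper width of the projected curve along the
  in-plane direction orthogonal to the APD axis.
* **TTD** (mm): straight 3D chord between the trigone markers.
* **SI** = APD/ICD; **LAI** = TLL/APD at late systole, where TLL is the
  summed aortic and parietal leaflet length.

APD and ICD are measured in projection (which makes "orthogonal to the
APD" well defined) while TTD is a 3D chord; for flat rings the conventions
agree. Whether clinical workstations measure the former two in 3D or in
projection is not standardised; the in-plane choice is ours and is
documented rather than inferred. A self-intersecting projected ring (a
degenerate landmarking) is flagged with a warning but still measured, so
one bad frame does not abort a batch.

## Volumetrics, MR severity, and arterial load

With no relevant right-sided regurgitation, the right-ventricular total
stroke volume is a surrogate for the LV forward stroke volume, so

$$\mathrm{TSV} = \mathrm{LVEDV} - \mathrm{LVESV}, \quad
  \mathrm{EF} = \mathrm{TSV}/\mathrm{LVEDV}, \quad
  \mathrm{RVol} = \mathrm{TSV}_{LV} - \mathrm{TSV}_{RV}, \quad
  \mathrm{RF} = \mathrm{RVol}/\mathrm{TSV}_{LV}.$$

A negative RVol is physiologically implausible but is returned unclipped
(with a warning) so that downstream paired statistics remain unbiased.

Arterial load is summarised two ways: arterial elastance
$E_a = \mathrm{MBP}/(\mathrm{FSV}/\mathrm{BW})$ with
$\mathrm{FSV} = \mathrm{VTI} \times \mathrm{CSA}_{AV}$ (mmHg/mL/kg; the MBP
is the recorded oscillometric mean, not derived from SAP/DAP), and the
aortic distensibility index
$\mathrm{ADI} = \frac{(A_{max}-A_{min})/A_{min}}{\mathrm{SAP}-\mathrm{DAP}}$
(mmHg⁻¹, reported ×10³). The fractional area change is taken relative to
the diastolic (minimal) area, the usual convention for distensibility
indices; using the mean area instead would rescale the index by ~10%.

**Allometric indexing.** Linear measures are divided by BW^(1/3)
(mm/kg^(1/3)), areas are converted to cm² and divided by body surface area
(cm²/m²), volumes by BW (mL/kg). Canine BSA uses the standard allometric
form BSA = 0.101·BW^(2/3) m²; the constant is a package-level choice
(recorded in `canineBSA()`), and changing it rescales all area indices
uniformly.

## Paired statistics

For each variable (per phase for annular metrics), differences are defined
**pre − post** (a decrease after treatment is positive). The routing rule
(`normalityGate()`) is a Shapiro–Wilk test on the differences at α = 0.05:
p ≥ 0.05 uses the paired t-test, otherwise the Wilcoxon signed-rank test.
Visual Q-Q inspection, which often accompanies Shapiro–Wilk in practice, is
not automatable and is deliberately excluded from the gate. Choices worth
making explicit:

* **Wilcoxon conventions.** Zero differences are dropped (Wilcoxon's
  rule), tied absolute differences are midranked, and the two-sided p is
  exact — computed by dynamic programming over doubled midranks — for up to
  25 non-zero differences, with a continuity-corrected normal approximation
  (midrank variance) above. The exact routine is verified against full
  2ⁿ sign enumeration in the tests. `stats::wilcox.test` declines exact
  p-values under ties/zeros, which is why the routine is implemented here.
* **CIs.** The mean difference with its t-based 95% CI is always reported,
  including for variables routed to Wilcoxon (flagged nonparametric and
  summarised as median + IQR). Degenerate inputs: a constant difference
  vector is routed nonparametric with normality p = 0; identical pre/post
  yields difference 0 with p = 1.
* **No multiplicity adjustment.** Each variable is tested at α = 0.05 on
  its own, as is typical for small paired cohort studies; with ~40
  variable×phase cells, a family-wise reading of the flags is optimistic
  and users should interpret accordingly.
* **Systolic behaviour.** A metric's ES-vs-ED relative change classifies
  expansion (> +1%), contraction (< −1%) or none. The 1% dead band guards
  per-subject calls against noise-driven sign flips; on cohort means the
  sign is what matters. The classification is invariant to indexing since
  the denominators cancel.

## The synthetic cohort generator

`generateCohort()` emulates the structure the analysis assumes, with every
ground-truth parameter exposed (`defaultCohortConfig()`):

* **Annulus.** The saddle family x = a·cosθ, y = b·sinθ, z = h·cos2θ — the
  simplest closed curve with two horns and two commissural lows — with
  closed forms MAA → πab, APD → 2a, ICD → 2b, SI → a/b that make oracle
  tests possible. Semi-axes are parametrised in indexed units and scaled by
  BW^(1/3) per subject, so indexed summaries are body-size independent by
  construction. The per-phase defaults are calibrated so the pre-treatment
  indexed panel reproduces a published preclinical-MMVD cohort's means
  (e.g. end-systolic APDi ≈ 11.0, MAAi ≈ 9.7 with systolic expansion
  relative to ED); saddle height is fixed at 1.2 mm/kg^(1/3), a mid-range
  value that keeps horn detection on the elevation path.
* **Trigones and TTD.** Trigone markers are the grid markers nearest
  ±π/4, giving an indexed trigone chord ≈ 8.0 mm/kg^(1/3). With 16
  uniformly spaced markers on an ellipse the chord can only take values
  2b·sin(kπ/8), and the published chord (≈ 6.2) falls between the k = 1 and
  k = 2 positions; we accept the k = 2 value rather than distort the marker
  grid. This is the one pre-treatment summary the ellipse-saddle family
  cannot match; all qualitative TTD behaviour (constancy through the cycle
  and under treatment) is preserved by pinning trigone markers at their
  unmultiplied positions.
* **Volumes and hemodynamics.** LVEDVi 4.21 mL/kg, total EF 0.64,
  RF 0.371, built so LV TSV = RV TSV + RVol holds exactly before noise; LA
  volumes are generated as a minimal volume plus a strictly positive
  filling volume (so LAESV ≥ LAEDV structurally); pressures around MBP
  89.5 mmHg; aortic fractional area change 0.242 (ADI×10³ ≈ 5.4). The echo
  forward stroke volume equals the RV TSV surrogate, giving Ea ≈ 53
  mmHg/mL/kg, within one cohort SD of the published estimate.
* **Treatment effects.** Post-visit systolic semi-axis multipliers
  (ES: a×0.906, b×0.934; LS: 0.950/0.955; MS b×0.976) — equivalent to
  programmed indexed ES APD and ICD reductions of 1.03 and 0.75 — plus
  additive indexed volume effects (LVEDVi −0.52, LVESVi −0.28, RF −0.0975,
  LA volumes down) with diastolic geometry, TLL, trigones and pressures
  untouched. These values reproduce the published post-treatment pattern:
  the cohort-mean MAA flips from systolic expansion (≈ +14% noiseless) to
  contraction (≈ −4%).
* **Noise.** Subject-level Gaussian random effects shared between visits
  (the paired structure), visit-level Gaussian measurement noise added
  last, and isotropic marker jitter (0.3 mm) plus a seeded random rigid
  transform per landmark set. No error model is published for these
  measurements; the SDs are set so cohort SDs and paired-difference SDs are
  of the published order (e.g. indexed ES APD difference SD ≈ 1.0). RF and
  small LA volumes are floored (0.01/0.02) so that multi-thousand-cohort
  simulation runs cannot produce non-physiologic values; with default SDs
  the floors bind with probability ≪ 1%.

What the generator does **not** emulate: non-elliptical annular cross
sections (hence the TTD compromise), correlated marker placement error
(real manual landmarking errs along the annulus, not isotropically),
phase-registration error, breed structure in body weight (only the
published range is known, so BW is uniform on 4.3–19.6 kg), and any direct
biomechanical link between annular size and regurgitant orifice (annular
and volumetric effects are programmed independently). Passing recovery and
calibration tests therefore demonstrates correctness of the pipeline's
arithmetic and statistics under the stated noise model, not robustness to
real-world landmarking pathology.

## Numerical choices and degenerate inputs

* Ring resampling uses a 2048-point dense pass to invert arc length;
  closed-form agreement at 16 markers is ~0.003%, far inside the 1% test
  tolerance.
* The flat-ring fallback threshold is 0.05 mm of maximal elevation —
  far below any physiologic saddle height (~2–3 mm for a 10 kg dog) but
  above reconstruction noise on a truly flat ring.
* Self-intersection of the projected ring is detected on a 128-vertex
  subsample by pairwise proper segment crossing; it is a degeneracy
  detector, not an exact geometry routine.
* Ties in `phaseOfMinimum()` break toward the earlier phase.
* `EF = 1` (LVESV = 0) is allowed arithmetically but flagged implausible.
* Exact Wilcoxon enumeration is limited to 25 non-zero differences
  (distribution size ≤ sum of doubled ranks, trivially fast by DP); beyond
  that the continuity-corrected normal approximation differs from the
  exact p by < 0.02 at n = 30 in the tests.

## Problem sizes used in the shipped checks

The package's own verification uses cohorts of n = 20 subjects (the
published cohort size): one full landmark-reconstruction cohort
(20 × 2 visits × 6 phases = 240 rings at M = 512), type-I error over 2000
measurement-level null cohorts, and CI coverage of the programmed ES APD
effect over 1000 cohorts. The measurement-level mode reuses the saddle
closed forms plus the identical noise model instead of re-running spline
reconstruction, which the geometry tests separately bound to < 1% error;
this keeps the calibration studies to seconds while the end-to-end
landmark route is exercised on single cohorts.

## Limitations

The package starts at landmarks: no DICOM handling, segmentation or
automatic marker placement. Annular height/non-planarity angles are not
computed. The RVol/RF method assumes no relevant right-sided or aortic
regurgitation; Ea and ADI are load estimates unvalidated against invasive
measurements; oscillometric pressures carry their usual inaccuracy. The
comparison table mirrors the unadjusted-multiplicity reporting style of
small clinical cohorts.
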