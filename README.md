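# mitralCT

Landmark-based quantification of mitral annular dynamics and mitral
regurgitation from ECG-gated cardiac CT in dogs.

In canine myxomatous mitral valve disease (MMVD), the mitral annulus (MA)
can lose its normal systolic contraction and instead expand during systole,
worsening regurgitation. Given 16 ordered 3D markers placed around the
annulus (with the two fibrous trigones flagged) at several cardiac phases,
plus biventricular volumetry, pressures and aortic Doppler, `mitralCT`
computes the full analysis chain used in clinical research on this
question. It is aimed at veterinary-cardiology imaging researchers who have
landmark and volumetric exports and want a reproducible, tested path from
those files to a publication-style paired pre/post comparison.

## What it computes

**Annular geometry** (per subject/visit/phase, from a closed periodic cubic
spline through the 16 markers, projected onto its total-least-squares
plane):

- MAA — projected annular area (shoelace formula), mm²
- APD — in-plane distance between the aortic and parietal saddle horns
  (maximal-elevation point of each trigone-delimited portion), mm
- ICD — maximal caliper width orthogonal to the APD axis, mm
- TTD — 3D chord between the trigone markers, mm
- SI = APD/ICD; LAI = (aortic + parietal leaflet length)/APD at late systole

**MR severity and hemodynamics**: TSV = LVEDV − LVESV, EF = TSV/LVEDV,
RVol = LV TSV − RV TSV (RV TSV as forward-stroke-volume surrogate),
RF = RVol/LV TSV; arterial elastance Ea = MBP/(FSV/BW) with
FSV = VTI × AV CSA; aortic distensibility index
ADI = ((A_max − A_min)/A_min)/(SAP − DAP), reported ×10³ mmHg⁻¹.

**Allometric indexing**: linear / BW^(1/3), area (cm²) / BSA
(BSA = 0.101·BW^(2/3) m²), volume / BW.

**Paired statistics**: differences pre − post, Shapiro–Wilk gate at
α = 0.05 routing to paired t or exact Wilcoxon signed-rank (zeros dropped,
midranks, exact null distribution up to n = 25), mean differences with
t-based 95% CIs, publication-style tables.

**Synthetic cohorts**: `generateCohort()` simulates paired cohorts from a
saddle-ring family (x = a·cosθ, y = b·sinθ, z = h·cos2θ) with known ground
truth, calibrated to a published 20-dog preclinical-MMVD cohort, for
effect-recovery, coverage and type-I-error verification.

## Worked example

Metric panel for one end-systolic landmark ring (here built analytically;
real rings come from `readLandmarks()` on JSON/CSV exports):

```r
library(mitralCT)
th <- 2 * pi * (0:15) / 16
lm <- AnnulusLandmarkSet(cbind(14.2 * cos(th), 15.1 * sin(th), 2.6 * cos(2 * th)),
                         trigoneIndices = c(15L, 3L), subjectId = "dog01",
                         visit = "pre", phase = "ES")
round(annulusMetrics(lm)[, c("MAA", "APD", "ICD", "TTD", "SI")], 2)
#>      MAA  APD  ICD   TTD   SI
#> 1 673.56 28.4 30.2 21.35 0.94
```

A 28.4 × 30.2 mm annulus with a 673.6 mm² projected area and SI 0.94
(nearly circular). Indexing for a 9.84 kg dog gives MAAi
`indexMeasurement(673.56, "area", 9.84)` = 14.52 cm²/m² and APDi 13.25
mm/kg^(1/3). Volumetric MR quantification:

```r
sv <- strokeVolumeEF(41.4, 15.0)   # LVEDV, LVESV (mL)
mr <- mitralRegurgitation(sv$TSV, 16.6)  # RV TSV (mL)
#> TSV 26.4 mL, EF 0.638, RVol 9.8 mL, RF 37.1 %
```

End-to-end on a simulated 20-dog cohort (landmark reconstruction, indexing,
gated paired statistics):

```r
coh <- generateCohort(defaultCohortConfig(), seed = 17)
res <- analyzeCohort(coh, variables = c("APDi", "MAAi", "RF_pct", "LVEDVi"),
                     phases = c("ED", "ES"))
res$formatted
#>  Variable Phase Pre                 Post                MeanDiff CI95         P     Test     Flag
#>  APDi     ED    10.18, 9.61 - 10.85 10.17, 9.08 - 10.79 0.25     -0.24, 0.73  .43   wilcoxon
#>  APDi     ES    11.55 ± 1.21        10.30 ± 1.15        1.25     0.75, 1.74   <.001 paired_t *
#>  MAAi     ED    9.41 ± 1.75         9.30 ± 1.50         0.11     -0.55, 0.78  .724  paired_t
#>  MAAi     ES    10.54 ± 1.66        8.98 ± 1.78         1.56     1.00, 2.13   <.001 paired_t *
#>  RF_pct         34.58 ± 11.70       24.64 ± 11.63       9.94     6.65, 13.23  <.001 paired_t *
#>  LVEDVi         4.29 ± 0.59         3.72 ± 0.56         0.56     0.36, 0.77   <.001 paired_t *
```

The programmed treatment effect is recovered: end-systolic annular
dimensions and MR severity fall (positive pre − post differences, p < .001)
while end-diastolic geometry shows no detectable change — the
"pharmacologic annuloplasty" pattern. A shell entry point wrapping the same
functions (`simulate` / `measure` / `compare` / `report`) is installed at
`inst/scripts/mitralct`.

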