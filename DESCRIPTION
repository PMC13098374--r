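Package: mitralCT
Title: Mitral Annular Dynamics and Regurgitation Quantification from Cardiac CT Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Landmark-based analysis of canine mitral annular geometry across
    the cardiac cycle from ECG-gated cardiac computed tomography. Reconstructs
    a saddle-shaped annulus ring from 16 ordered 3D markers, computes projected
    annular area, aortoparietal, intercommissural and trigone-to-trigone
    distances, sphericity and leaflet-to-annulus indices, quantifies mitral
    regurgitation volumetrically from biventricular stroke volumes, derives
    arterial elastance and an aortic distensibility index, applies allometric
    body-size indexing, and runs normality-gated paired pre/post-treatment
    statistics. Includes a synthetic cohort simulator with known ground truth
    for calibration and effect-size recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils-geometry.R'
    'AllClasses.R'
    'AllGenerics.R'
    'annulus-geometry.R'
    'volumetrics.R'
    'hemodynamics.R'
    'dynamics-profile.R'
    'paired-stats.R'
    'synthetic-cohort.R'
    'measure-cohort.R'
    'io.R'
    'cli.R'
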