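Package: sbrtdose
Title: Dosimetric Evaluation and Algorithm-Adapted Guidelines for Lung SBRT Plans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes RTOG/NRG plan-quality metrics for stereotactic body
    radiotherapy (SBRT) lung treatment plans from 3D dose grids and structure
    masks: DVH statistics (D95%, V100%, V90%, near-minimum dose, V105%),
    conformality index, R50 dose falloff, and D2cm via an exact Euclidean
    distance transform. Classifies protocol deviations against
    volume-interpolated RTOG 0813/0915 thresholds, renormalizes plans to a
    prescription coverage target, derives dose-calculation-algorithm-adapted
    guideline tables by cohort-mean ratio scaling, and runs paired cohort
    statistics. Includes a synthetic paired-plan cohort generator emulating
    the coverage and conformality shifts seen when convolution-algorithm
    plans are recalculated with a linear Boltzmann transport equation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
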