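Package: txdose
Title: Treatment Dose Reconstruction from 3D/4D Cone-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale toolkit for reconstructing delivered radiotherapy
    dose from daily 3D/4D cone-beam CT (CBCT). Implements phase-matched
    deformable registration of planning 4D-CT to daily 4D-CBCT (block-matching
    initialisation followed by local-correlation-coefficient refinement),
    displacement-field inversion and field-of-view expansion, pseudo-CT
    synthesis with intensity overrides and outside-FOV patching, a simplified
    ray-marching dose engine, per-phase dose warping and accumulation across
    fractions and replan chains, and quantitative registration/dose QA
    (target registration error, DICE, mean surface distance, DVH metrics).
    Ships a synthetic breathing-thorax phantom with exact ground-truth
    deformations so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    xml2,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
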