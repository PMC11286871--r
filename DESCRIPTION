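Package: adolmat
Title: Adolescent Cortical Myelin Maturation and Resilient Psychosocial Functioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking longitudinal change in residual-based resilient
    psychosocial functioning to cortical myelin-proxy (magnetization transfer,
    MT) maturation in accelerated longitudinal cohorts. Implements latent
    distress factor scoring, nested cross-validated prediction of distress from
    adversity with residual extraction, equivolumetric intracortical depth
    sampling with CSF partial-volume correction, microstructural profile
    covariance (MPC) networks, per-parcel longitudinal general linear models
    with permutation and FDR inference, edge-wise linear mixed models yielding
    a maturational index, a diffusion-map axis of age effects, and group
    comparisons of maturational indices, together with a synthetic-cohort
    generator with planted ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ranger
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
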