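Package: sncvigor
Title: Lateralized Nigral Dopamine Activity and Movement-Sequence Vigor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-forelimb operant lever-press behavior
    combined with one-photon calcium imaging of substantia nigra pars compacta
    dopaminergic neurons. Segments lever presses into snout-gated sequence
    bouts, builds peri-event time histograms, classifies neurons as
    movement-initiation, execution, reward or magazine-approach modulated with
    a consecutive-bin percentile rule, matches ROIs across daily sessions by
    centroid proximity with shuffled and different-ROI correlation controls,
    tests laterality and sequence-length coding of pre-movement activity, and
    quantifies the behavioral contrast of a unilateral dopaminergic lesion.
    Includes a synthetic-data generator emulating the task and GCaMP6f-like
    transients so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
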