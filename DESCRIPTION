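Package: biomotion
Title: Simulation and Analysis of Point-Light Biological Motion Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing point-light biological motion stimuli
    (parametric articulated figures, spatial scrambling, graded perturbation
    morphs, trajectory-matched noise masks), for running the psychophysical
    procedures used to probe their perception (a transformed two-up/one-down
    adaptive staircase, paired constant-stimuli discrimination, yes/no
    categorization scored with equal-variance signal detection theory), and
    for simulating and analysing event-related and block-design BOLD fMRI on
    a synthetic voxel lattice (double-gamma hemodynamic responses, GLM
    contrasts, false-discovery-rate ROI definition with contiguity filtering,
    event-related averaging and peak percent signal change). Human
    participants are replaced throughout by parametric simulated observers
    with control-like and patient-like presets, so every analysis is
    exercisable end to end without behavioural or imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
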