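Package: proton4d
Title: Respiratory-Motion Compensation for Passively Scattered Proton Therapy Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study and compensate respiratory motion in passively
    scattered (double-scattering) proton therapy of mobile liver tumors. The
    package generates deterministic synthetic 4D CT phase series of a moving
    liver dome, derives average (AVG), maximum-intensity-projection (MIP) and
    density-override (OVR) planning volumes with ITV/PTV structures, converts
    Hounsfield units to relative proton stopping power, designs per-field
    apertures, range compensators and spread-out Bragg peaks with a broad-beam
    water-equivalent path-length dose engine, and builds the field-specific
    distal-margin plan (mAVG) whose margins are the MIP-minus-AVG range
    differences. Plans are evaluated by per-phase dose recomputation with
    frozen beam hardware, target dose indices (D95%, D99%, D100%), conformity
    index, dose-volume histograms, equal-weighted 4D dose composition, and a
    +/- 2 percentage-point acceptability criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    pracma,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate: 
    'proton4d-package.R'
    'AllClasses.R'
    'utils.R'
    'volumes.R'
    'beam-model.R'
    'ct-ops.R'
    'dose-engine.R'
    'planning.R'
    'evaluation.R'
    'io.R'
    'phantom.R'
    'plots.R'
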