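Package: tacsloop
Title: Closed-Loop tACS-fMRI Protocol Simulation and Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation of a closed-loop transcranial alternating
    current stimulation (tACS) protocol with concurrent real-time fMRI.
    Provides the dual-site high-definition 4x1 electrode montage with its
    current-budget constraints, an analytic quasistatic electric-field model
    (point-current-source superposition in a homogeneous half-space, midpoint
    shunt estimate, and a focality-volume metric), block-design session
    schedules, a synthetic two-ROI BOLD generator with a hidden
    stimulation-parameter response surface and realistic nuisance structure,
    an online windowed-connectivity engine (nuisance regression, Pearson
    correlation with Fisher r-to-z), and a Nelder-Mead simplex optimizer over
    integer stimulation parameters with failure counting and triangle
    restarts, orchestrated into full maximize/minimize closed-loop protocols.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
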