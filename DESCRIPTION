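Package: spinemorph
Title: Spine Morphometry, Permutation Testing, Proteome Filtering and
    Calcium-Transient Kinetics for a Mouse Muscle-Spindle Study Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for quantifying murine spinal deformity from
    vertebral landmark point clouds: flat-ended (natural) cubic-spline centerline
    fitting, curvature and radius-of-curvature profiles, analytic Cobb angles in
    named anatomical planes, and two-sample permutation tests on per-spine
    curvature summaries. Also implements a fold-change/q-value differential-
    protein retention rule and kinetic analysis (dF/F0, time to peak, half time
    to peak, half relaxation time) of stimulus-evoked calcium transients, with
    seeded synthetic-data generators for every stage so the full analysis runs
    without access to raw micro-CT, proteomics or imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
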