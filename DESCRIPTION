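Package: dynbody
Title: Voxel-Wise Encoding Models of Dynamic Body Perception
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for voxel-wise encoding models
    of dynamic body-movement perception. Generates synthetic motion-capture
    skeletons with biomechanically possible and impossible (mirrored
    elbow/knee) joint trajectories, stick-figure stimulus videos, event-
    related fMRI designs and BOLD time series with known ground truth.
    Computes four stimulus feature spaces (3D keypoints, Gaussian-kernel
    similarity distance to a manifold of normal movements, categorical
    possibility indicators, and spatiotemporal Gabor motion energy), fits
    banded ridge regression with nested run-wise cross-validation, partitions
    the jointly explained variance into per-feature-space contributions,
    builds composite HSV maps, and performs group inference via sign-flip
    permutation tests, FDR correction, paired contrasts with effect sizes and
    retrospective power, and three-way repeated-measures ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
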