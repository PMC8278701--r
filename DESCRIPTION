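Package: swayrate
Title: Automatic Balance-Exercise Rating from Trunk-Worn IMU Angular Velocity
Version: 0.1.0
Authors@R: person("swayrate", "maintainers", email = "maintainers@swayrate.dev", role = c("aut", "cre"))
Description: Estimates a physical therapist's ordinal rating (1-5) of a 30 s
    standing-balance exercise from the pitch/roll angular-velocity signal of a
    single trunk-worn inertial measurement unit. Provides the kinematic sway
    descriptors used in feature-based balance assessment (RMS sway, path
    length, 95% confidence-ellipse area), time-series and trajectory-image
    representations of the raw signal, a depth-wise 1-D/2-D convolutional
    classifier and a random-forest classifier with their training protocol,
    a severity-graded synthetic posturography generator with a noisy
    multi-rater ordinal labeling process, and the evaluation protocol
    (macro-averaged AUROC, random-rater and majority baselines,
    Krippendorff's alpha, paired multi-restart comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
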