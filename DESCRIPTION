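Package: naturalreach
Title: Behavioral State Segmentation and Event-Related Spectral Analysis of Naturalistic Arm Movements
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to segment wrist trajectories into move and rest states with an
    autoregressive hidden semi-Markov model, detect and prune movement-initiation
    events, preprocess multichannel intracranial recordings, compute event-related
    Morlet spectral power with baseline normalization, project electrode-level power
    onto atlas regions with Gaussian weights, mask group spectrograms by a bootstrap
    baseline null with FDR correction, extract per-event behavioral and environmental
    features, and regress event-by-event band power on those features with Huber loss,
    forward selection, and permutation feature importance. A synthetic-study generator
    with known ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
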