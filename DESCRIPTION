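Package: signfuse
Title: Sign-Language Word Recognition from sEMG and Inertial Motion Signals
Version: 0.1.0
Authors@R:
    person("signfuse", "developers", email = "signfuse@example.org",
           role = c("aut", "cre"))
Description: Segments continuous multimodal recordings (4-channel surface
    electromyography plus a triaxial accelerometer and gyroscope at the
    wrist) into word-level activity segments by dual-signal absolute-mean
    sliding-window thresholding, and recognizes each word by decision
    fusion of a gesture stream and a movement-trajectory stream with a
    two-chain coupled hidden Markov model. Words are modeled as ordered
    stages of composite (gesture, trajectory) states; the package includes
    a lexicon data model, a seeded synthetic-recording generator with
    ground truth, exact composite-lattice inference with Baum-Welch
    training, and an end-to-end simulate/train/evaluate pipeline with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
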