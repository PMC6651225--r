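Package: micaps
Title: Motor Imagery EEG Classification with Capsule Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete pipeline for two-class (left vs right hand) motor
    imagery EEG decoding with capsule networks. Cue-locked trials are
    band-pass filtered (4-38 Hz), epoched 0.5-2.5 s after the cue, and
    converted to 3-channel 14x14 time-frequency images by short-time
    Fourier transform. A capsule network with dynamic routing by
    agreement, margin loss and a reconstruction regularizer classifies
    the images; a ShallowNet convolutional baseline consumes the raw
    epochs. A synthetic generator of contralateral mu/beta event-related
    desynchronization trials makes every stage testable without external
    recordings. All forward and backward passes are implemented in
    vectorized R and trained with momentum SGD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
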