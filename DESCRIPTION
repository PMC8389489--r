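Package: eegsel
Title: Unsupervised Spatiotemporal Feature and Channel Selection for
    Subject-Independent EEG Affect Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A subject-independent pipeline for recognising affective state
    (binary valence and arousal) from multi-channel EEG. Provides a synthetic
    EEG generator with planted class effects, zero-phase preprocessing
    (notch, band-pass, ICA-based ocular removal, polyphase down-sampling,
    epoching), a 54-feature battery per epoch and channel (time, frequency
    and wavelet domains), unsupervised Laplacian-score feature ranking, an
    affinity-propagation channel-selection algorithm that clusters channels
    by feature-space correlation, discounts spatially close pairs on the
    montage graph and ranks channels by cross-epoch consistency, mutual
    information best-k refinement, and leave-one-subject-out nested
    cross-validation with a support vector machine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    pracma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
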