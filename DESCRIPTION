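Package: sdcmem
Title: Sparse Distributed Coding Memory for Binary Frame Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical associative memory for spatiotemporal sequences of
    binary frames, built from macrocolumn-like modules (macs) of winner-take-all
    minicolumns (competitive modules). Each frame, a fixed-time code selection
    algorithm converts a module's bottom-up, horizontal and top-down inputs into
    a sparse distributed code via a familiarity-modulated softmax, storing new
    moments with single-trial Hebbian learning (effectively binary synapses with
    age/permanence dynamics and per-module critical periods) and retrieving the
    best-matching stored moment in fixed time. A back-off match policy confers
    tolerance to nonlinear time warping of test sequences. Includes synthetic
    sequence generators, accuracy metrics, and benchmark drivers for noisy
    best-match retrieval and similar-inputs-to-similar-codes studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
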