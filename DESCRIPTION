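Package: signia
Title: Interactive Activation Modeling of Sign Language Recognition
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates lexical access in sign language recognition with a
    two-layer interactive activation and competition network in which
    lateral inhibition between lexical units is gated by a steep sigmoid
    of the sending unit's activation, so weakly active neighbors net-
    facilitate a target sign (through shared sub-lexical feedback) while
    strongly active neighbors net-inhibit it (through lexical
    competition). Provides deterministic network construction for targets
    with location/orientation/handshape/movement sub-lexical slots and
    configurable neighborhoods, input scheduling with staggered onsets,
    three canned simulation protocols (sub-lexical input timing,
    sub-lexical resting activation, neighborhood density), net-effect
    measurement against matched no-neighbor baselines, robustness sweeps,
    polarity-boundary bisection, JSON configuration and CSV trajectory
    output, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
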