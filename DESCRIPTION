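Package: MMNmAdditivity
Title: Additivity Analysis of Magnetic Mismatch Responses in Multi-Feature
    Oddball Paradigms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying the additivity of the magnetic mismatch
    negativity (MMNm) elicited by multi-feature auditory oddball paradigms.
    The package generates complex (Alberti-bass) and simple control oddball
    block sequences, simulates planar-gradiometer MEG epochs with a known
    ground-truth subadditivity coefficient, preprocesses epochs (SQUID-jump
    rejection, zero-phase Butterworth band-pass, root-mean-square planar
    combination, baseline correction), constructs empirical and modeled
    (sum-of-singles) mismatch difference waves, and tests additivity and
    additivity-by-expertise interactions with nonparametric spatiotemporal
    cluster-based permutation statistics, including exhaustive small-sample
    oracles, type-I-error and power experiments, and recovery of the
    subadditivity coefficient.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, signal, jsonlite
Suggests: testthat (>= 3.0.0), igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
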