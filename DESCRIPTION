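Package: quantmlp
Title: Fixed-Point MLP Inference with Cycle-Level Latency Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bit-exact simulation of a low-latency multi-layer perceptron
    (MLP) inference processor for mass-spectrometry proteomic diagnostics.
    Provides post-training quantization of trained float MLPs to 8-bit
    weights and 32-bit biases, a functional model of the blocked
    matrix-vector datapath (scalar-product adder trees, accumulation,
    streaming max search, leading-one detection and truncation
    requantization), a closed-form cycle-count latency model parameterized
    by the block dimensions (M, N), a counter-driven control-schedule
    simulator cross-validating the closed form, a design-space explorer
    that selects (M, N) under a multiplier budget, and a generator of
    synthetic two-class SELDI-like intensity spectra with a minimal
    reference trainer so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
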