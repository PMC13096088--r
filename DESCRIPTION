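Package: greenwarn
Title: Environment-Guided Early Disease Warning for Greenhouse Crops
Version: 0.1.0
Authors@R: person("Greenhouse", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A joint visual-environment perception toolkit for early disease
    warning in protected horticulture. Provides a synthetic greenhouse
    multimodal simulator (minute-resolution climate streams, procedural leaf
    imagery with staged lesions), temporal alignment and smoothing of sensor
    streams to image timestamps, a dual-branch neural network in which
    environmental embeddings gate visual channel responses and a
    spatial-temporal attention stack models disease evolution, a four-term
    joint training objective, and an early-warning evaluation suite including
    a hysteresis-based lead-time metric and leakage-free event-level
    cross-validation. The network and its reverse-mode differentiation engine
    are implemented in base R matrix algebra, so the full pipeline runs on a
    single CPU without external deep-learning runtimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    png,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
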