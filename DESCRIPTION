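Package: bmtpp
Title: Burst and Memory-Aware Transformer for Temporal Point Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling bursty event sequences as temporal point
    processes. Provides the inter-event-time heterogeneity statistics
    (burstiness, finite-size-corrected burstiness, and the lag-1 memory
    coefficient), Farlie-Gumbel-Morgenstern copula samplers that generate
    event sequences with power-law or exponential inter-event times under a
    target memory coefficient, Hawkes and self-correcting process
    simulators, and a burst- and memory-aware transformer encoder that
    embeds discretized burstiness/memory tokens alongside sinusoidal time
    encodings and is trained with a five-part objective (event-time error,
    point-process log-likelihood, token cross-entropy, and squared errors
    of the burstiness and memory values). Includes an ablation harness over
    the embedding/loss variants, JSON Lines dataset IO, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
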