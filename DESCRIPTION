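Package: thetaring
Title: Theta-Modulated Plasticity and Replay in Ring Networks of Place Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates recurrent networks of hippocampal place cells on periodic
    (ring-like) tracks with spike-timing-dependent plasticity (pairwise and
    triplet trace rules), short-term synaptic depression, theta-modulated
    place-field input and stochastic virtual-animal motion. Provides the
    closed-form mean-field theory for the slow growth of the Fourier modes of
    the recurrent connectivity under constant or oscillating drive, the linear
    stability analysis of the quiescent state (traveling-wave/replay
    instability, with and without depression), the sequential-correlation (SC)
    statistic with shuffle nulls for detecting ordered reactivation, and a
    place-field characterization pipeline (cosine tuning fits, tuning-index
    selection, phase ordering) together with a synthetic-recording generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
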