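Package: antnav
Title: Agent-Based Simulation of Ant Visual Route Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates view-based route navigation in ants. Procedurally
    generates tree-populated worlds rendered as low-resolution greyscale
    panoramas, encodes training routes in a one-layer Infomax familiarity
    network, shapes learning routes with behavioural heuristics (beacon
    aiming, restricted field of view, gated oscillations, goal-directed
    learning walks) and recapitulates them with view-based orientation,
    familiarity-based modulation, or cast-and-surge controllers, optionally
    with familiarity-modulated scan ranges. Includes displacement-trial
    protocols and convergence metrics (route displacement, goal-region
    displacement, rapid-divergence classification, scan-effort statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
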