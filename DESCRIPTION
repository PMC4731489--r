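Package: multierp
Title: Simulation and Analysis of a Gamified Multi-ERP Oddball Paradigm
Version: 0.1.0
Authors@R: person("ERP", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing a gamified
    audiovisual oddball paradigm that elicits ten event-related potentials
    (C1, P50, MMN, N1, N170, P2, N2pc, LRP, P300, ERN) in a single session.
    Provides a seeded generator for the full three-level trial/block/event
    schedule with structured condition markers, programmatic two-tone
    stimulus images (checkerboards, Kanizsa figures, synthetic Mooney-style
    stand-ins) with mean-luminance equalisation, a multichannel EEG
    simulator that injects condition-dependent ERP templates on a 1/f
    background together with a behavioural response model, and an analysis
    chain covering filtering, epoching, baseline correction, average
    re-referencing, threshold epoch rejection, condition-averaged ERP
    contrasts (including LRP and N2pc derivations), event-related spectral
    perturbation, inter-trial coherence, permutation tests (paired t and
    one-way repeated-measures ANOVA) with Benjamini-Hochberg FDR masking,
    and Cohen's d effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
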