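Package: h12switch
Title: Conformational State Analysis of Helix 12 Switching in Nuclear Receptor Trajectories
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the inactive-to-active conformational transition
    of a nuclear-receptor ligand-binding domain (helix 12 repositioning) from
    molecular-dynamics trajectories. Provides readers for multi-model PDB and
    XYZ coordinate streams, Kabsch rigid-body superposition and RMSD, geometric
    state criteria (C-beta pair distance and fitted helix RMSD), skew-normal
    cutoff derivation from pooled histograms, per-replica occupancy and
    dwell-time statistics, replica-level significance testing (Mann-Whitney U
    and indicator t tests), a two-state telegraph-process synthetic trajectory
    generator with ground truth, and a config-driven analysis pipeline with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
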