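Package: wormstim
Title: Analysis of Earthworm Giant-Fiber Responses to Electrical,
    Mechanical and Ultrasound Stimulation
Version: 0.1.0
Authors@R:
    person("wormstim", "Maintainers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for quantifying stimulus-evoked action potentials in the
    giant fibers (MGF/LGF) of the earthworm ventral nerve cord. Provides a
    ground-truth-labelled synthetic recording generator emulating the
    preparation (two bipolar electrode pairs plus a stimulus-artifact
    channel), zero-phase band-pass filtering and biphasic spike detection,
    conduction-velocity estimation with arrival-delay decomposition into
    time of propagation (TOP) and time of generation (TOG), success-rate and
    dose-response analyses for pulsed low-energy ultrasound (LEUS)
    protocols, and the nonparametric statistical assessment (Jarque-Bera
    screen, Wilcoxon-Mann-Whitney, Wilcoxon signed-rank) used to compare
    stimulation modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
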