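Package: catloop
Title: Modelling the Autophagy-Alpha-Catenin-YAP/TAZ Feedback Loop
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Numerical model of the feedback loop coupling macroautophagy,
    alpha-catenin protein levels and YAP/TAZ transcriptional activity as three
    nonlinear ordinary differential equations with saturation terms. Provides
    trajectory integration, parameter-sweep response surfaces over feedback
    strength and initial alpha-catenin, classification of the direction of the
    YAP/TAZ response to autophagy inhibition with bisection of the regime flip
    boundary, time-windowed YAP-autophagy correlation analysis, a synthetic
    multi-cell-line panel generator emulating densitometry and TEAD luciferase
    readouts with lognormal replicate noise, recovery of initial alpha-catenin
    and feedback strength from such panels, and a scanner for the LC3-interacting
    region (LIR) core consensus (W/F/Y)xx(I/L/V) in protein sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
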