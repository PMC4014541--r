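Package: glnbolus
Title: Whole-Body Glutamine Kinetics from a Stable-Isotope Tracer Bolus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates whole-body rate of appearance (Ra) and endogenous
    rate of appearance (endoRa) of glutamine from the enrichment decay
    curve that follows an intravenous bolus of [1-13C]glutamine, using a
    single-pool tracer-dilution model (Ra = Dose / AUC of atom percent
    excess versus time). Converts GC-MS ion-intensity ratios (m/z 432/431)
    into baseline-corrected atom-percent-excess curves, integrates them by
    trapezoid rules with mono-exponential tail extrapolation, and corrects
    for exogenous glutamine delivered by an alanyl-glutamine infusion.
    Includes a sampling-schedule representation with a protocol-sensitivity
    simulation, single- and two-pool synthetic curve generators with a
    calibrated measurement-noise model for validation, repeatability
    statistics (within-subject CV), and group comparisons (paired t,
    one-way ANOVA with Dunnett many-to-one contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    mvtnorm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    deSolve,
    optparse
Config/testthat/edition: 3
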