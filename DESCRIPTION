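Package: cvrsim
Title: Closed-Loop Cardiorespiratory Simulation of Exercise with a Ventricular Assist Device
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A lumped-parameter (0-D) closed-loop simulator of the human
    cardiovascular and respiratory systems for studying exercise hemodynamics
    in severe heart failure, with and without a continuous-flow left
    ventricular assist device (LVAD). The heart is modelled with time-varying
    elastance ventricles and contracting atria, the systemic and pulmonary
    circulations as Windkessel compartments with collapsible veins and a leg
    muscle pump, closed by a baroreflex with exercise resetting and
    sympathovagal imbalance, local metabolic vasodilation, ventilation
    control and alveolar/tissue gas exchange. An axial-pump pressure-flow
    characteristic couples the left ventricle to the aorta, allowing
    heart-pump interaction and pump-speed modulation studies, with tools for
    steady-state protocols, hemodynamic summaries, pressure-volume loop
    extraction and diastolic stiffness fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
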