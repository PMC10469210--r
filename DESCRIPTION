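Package: perfusim
Title: Reduced-Order Simulation of Myocardial Perfusion and Coronary Flow
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale simulator of myocardial blood perfusion. Couples a
    closed-loop lumped-parameter (0D) model of the left heart and systemic
    circulation, driven by time-varying elastance chambers and diode valves,
    to a reduced epicardial coronary network and a three-compartment Darcy
    porous-media model of the biventricular myocardium solved with linear
    finite elements. Reproduces diastolic-dominant coronary flow, myocardial
    blood flow (MBF) maps in mL/min/100mL, and the coronary flow steal caused
    by aortic regurgitation. Includes a synthetic truncated-ellipsoid
    biventricular mesh generator, Voronoi perfusion-territory partitioning,
    VTK/CSV/JSON output, and scenario comparison utilities.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
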