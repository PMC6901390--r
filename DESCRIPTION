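Package: cascadekin
Title: Kinetic Modelling of a Cell-Free Mannose to Lactic Acid Enzyme Cascade
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses a four-enzyme cell-free reaction cascade
    that converts D-mannose into L-lactic acid via an oxidative,
    non-phosphorylative route (aldohexose dehydrogenase, mannonate
    dehydratase, 2-keto-3-deoxygluconate aldolase and lactate
    dehydrogenase) with internal NAD+/NADH recycling.  Provides
    Michaelis-Menten rate laws with thermal enzyme deactivation, a
    thermodynamically consistent reversible aldol step, one-pot and
    sequential (timed enzyme addition) ODE simulation with conservation
    diagnostics, yield and titre arithmetic including spent coffee ground
    hydrolysate mass balances, generators for synthetic NMR relative-integral
    and HPLC concentration time courses, and nonlinear least-squares
    estimation of cascade parameters with multi-start and mechanism
    discrimination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
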