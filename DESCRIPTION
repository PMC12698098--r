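Package: thzskin
Title: Multilayer Modelling of the In Vivo Terahertz Response of Compressed Skin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates and fits the terahertz (THz) time-domain reflection
    response of human skin pressed against a quartz imaging window. Skin
    surface ridges are represented as a stack of skin-air effective-medium
    layers (Landau-Lifshitz-Looyenga mixing) over a bulk skin half-space;
    the complex reflectance of the stratified system is computed by a
    recursive Fresnel relation with an independent transfer-matrix
    cross-check. The air volume fraction of the topmost ridge layer acts
    as a skin-deformation parameter and is extracted from a series of
    measured pulses by Gaussian-process Bayesian optimisation of a
    least-squares pulse-matching loss. Includes a robustness analysis for
    choosing the number of ridge layers, frequency-domain attenuation
    diagnostics, and a fully synthetic occlusion-measurement generator
    for validation without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
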