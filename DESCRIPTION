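Package: aawt
Title: Bayesian Meta-Analysis of Aneurysm Wall Thickness Measured Under
    Contact Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Merges abdominal aortic aneurysm (AAA) wall thickness
    measurements acquired by different groups under different contact
    pressures, including studies available only as a sample mean and
    standard deviation, into a single posterior distribution of the
    undeformed wall thickness.  A Holzapfel-Gasser-Ogden model of radial
    tissue compression links contact pressure to the measured (deformed)
    thickness through a smooth response-surface emulator; a hierarchical
    lognormal model separates inter-patient from intra-patient
    variability; the sampling density of (mean, SD) of lognormal samples
    is computed exactly up to quadrature via its characteristic function;
    and posterior predictive utilities provide tail probabilities of low
    wall thickness, study-level undeforming corrections and inter-study
    range metrics.  A synthetic multi-study cohort generator with the
    same statistical structure makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
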