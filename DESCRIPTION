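Package: icerp
Title: Mass-Univariate ERP Analysis of Illusory-Contour Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for event-related potential (ERP)
    studies of Kanizsa-type illusory contours under a three-task, two-condition
    design. Provides a synthetic multi-subject EEG generator with 1/f noise,
    injected ERP components and ocular artifacts; the standard ERP
    preprocessing chain (epoching, EOG-based artifact rejection, average
    reference, zero-phase band-pass filtering, baseline correction,
    averaging); mass-univariate point-wise paired t statistical maps with
    temporal- and spatial-extent significance criteria; leave-one-subject-out
    definition of component time windows; and repeated-measures ANOVA with
    Greenhouse-Geisser correction plus paired post-hoc tests with effect
    sizes. Includes calibration studies (null false-positive rate, effect
    pattern recovery) and simple file interchange (events TSV, channel
    layouts, EDF, a columnar raw container).
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
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
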