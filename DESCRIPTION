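Package: cristamorph
Title: Quantitative Morphometry of Mitochondrial Cristae in Cryo-Electron Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying mitochondrial inner-membrane architecture in
    cryo-electron tomograms: synthesis of phantom tomograms with known ground
    truth (double membranes, cristae of defined shape and width, Gaussian noise,
    missing wedge), MRC volume input/output, projection-plane morphometrics
    (areas, densities, cristae-junction width and angle), template-bank
    cross-correlation estimation of crista membrane-to-membrane width,
    miniature subtomogram alignment and averaging, rule-based 3D cristae shape
    classification, and a normality-gated nonparametric group-comparison layer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
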