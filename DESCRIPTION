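Package: voxcal
Title: Voxel Tumour Growth Simulation and Calliper Measurement-Error Statistics
Version: 0.1.0
Authors@R:
    person("Preclinical", "Morphometry", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A stochastic cellular-automaton model of subcutaneous tumour
    growth and treatment on a 3D voxel lattice, a virtual-calliper measurement
    procedure that quantifies the bias of spheroid-formula volume estimation
    across six tumour morphologies, and the statistical toolkit used to
    compare manual calliper and 3D-scan tumour measurements: tumour growth
    inhibition (TGI) and AUC efficacy indices, inter-operator coefficient of
    variation and intra-class correlation, Bland-Altman volume-weight
    agreement, relative-error banding, and scan-calliper consistency counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
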