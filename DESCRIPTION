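Package: nvumorph
Title: Morphometry of the Retinal Neurovascular Unit from Segmented 3D EM Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative morphometry for segmented serial block-face scanning
    electron microscopy (SBF-SEM) stacks of retinal capillaries. Measures
    vascular basement-membrane thickness by 2D local thickness (largest
    inscribed disc) on each section, detects pericyte-endothelial
    peg-and-socket formations, cell-basement-membrane detachment events and
    intracytoplasmic endothelial tubules as anisotropy-aware 3D connected
    components, and normalises feature counts per 10 micrometres of capillary
    depth. Includes a synthetic capillary phantom generator with analytic
    ground truth for validation, cohort simulation, and the group statistics
    (mean plus or minus SEM, unpaired two-tailed Student's t and Mann-Whitney
    U tests) used to compare non-diabetic and diabetic groups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    tiff,
    yaml,
    jsonlite,
    EBImage,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
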