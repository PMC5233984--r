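Package: tcranchan
Title: Transcranial-Channel HD-tDCS Field and Neuron Polarization Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling of high-definition transcranial direct current
    stimulation (HD-tDCS) delivered through a conductive transcranial channel
    implanted in the skull. Builds parametric layered head geometries (and
    concentric-sphere phantoms) on a structured voxel grid, solves the
    quasi-static volume-conduction equation with a preconditioned conjugate
    gradient finite-element solver, decomposes the induced electric field into
    radial and tangential cortical components, and computes focality volumes.
    Couples the field solution to passive compartmental models of layer 5 and
    layer 3 pyramidal neurons to obtain steady-state membrane polarization and
    somatic coupling constants, and orchestrates channel-diameter and
    electrode-displacement experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
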