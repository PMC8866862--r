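Package: mandifix
Title: Finite-Element Evaluation of Mandibular Fracture Fixation Devices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates a parametric synthetic human mandible with fracture
    scenarios and miniplate/screw fixation, solves the orthotropic
    linear-elastic problem on quadratic tetrahedral (TET10) meshes under
    post-operative unilateral-clenching muscle loads, and post-processes
    healing-region principal strains and device von Mises stresses to
    compare titanium (Ti-6Al-4V), magnesium (WE43) and polylactic acid
    (PLA) osteosynthesis devices at two plate thicknesses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
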