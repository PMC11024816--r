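Package: tractmorph
Title: Whole-Volume White-Matter Tract Morphometry via Mesh Morphing
Version: 0.1.0
Authors@R: person("tractmorph", "developers", role = c("aut", "cre"),
    email = "maintainer@tractmorph.dev")
Description: Morphs a fixed-topology hexahedral template mesh of a white-matter
    tract onto per-subject tract geometry with host-lattice free-form
    deformation, embeds per-voxel diffusion tensor metrics (FA, MD, AD, RD)
    into the corresponded elements by nearest-neighbour search, and runs
    cohort-level analyses (standardized principal component analysis,
    element-wise t-test fields, mean +/- SD pattern fields) on the resulting
    fixed-dimension feature matrices. Ships a synthetic-cohort generator so
    the whole pipeline is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
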