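Package: phytophore
Title: Pharmacophore and Field-Similarity Virtual Screening of Natural-Product Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A sequential virtual-screening engine for triaging natural-product
    libraries against a structure-based pharmacophore, in the style used to
    search for dipeptidyl peptidase-IV (DPP-IV) inhibitors in annotated
    phytochemical collections. Provides pharmacophore representation and
    matching (with and without pose reorientation, with receptor-derived
    excluded volumes), Gaussian shape-Tanimoto and electrostatic-field-Tanimoto
    rescoring of docked poses against a reference inhibitor pose, MOLPRINT2D
    atom-environment fingerprints with hierarchical clustering and
    Kelley-criterion level selection for scaffold-novelty analysis, and
    natural-source/extract reporting. Includes deterministic synthetic-fixture
    generators so the full screening funnel is testable end to end without
    external docking software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    bio3d,
    stats,
    utils
Suggests:
    ChemmineR,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
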