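Package: aslregsim
Title: Simulation-Based Evaluation of ASL-to-T1w Registration and Regional
    Perfusion Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating arterial spin labeling (ASL) to structural
    T1-weighted image registration strategies on synthetic brain phantoms with
    known ground truth. Simulates pseudo-continuous ASL label/control series
    over ellipsoidal tissue phantoms, quantifies cerebral blood flow (CBF)
    with the single-compartment kinetic model, scores map quality with a
    quality evaluation index (QEI), and registers mean-CBF images to the
    structural volume by emulated-manual alignment, rigid intensity-based
    registration, and boundary-based refinement along the gray-white cortical
    interface. Downstream modules project CBF to the boundary surface,
    partition it into parcels, measure registration consistency through
    pairwise inter-subject Pearson correlations, and run region-of-interest
    group comparisons with Bonferroni control plus per-region severity
    regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
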