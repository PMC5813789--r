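Package: mxmerge
Title: Multi-Crystal X-ray Dataset Clustering, Scaling and Merging
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for assembling complete X-ray diffraction datasets from
    many partial or complete rotation sweeps collected on multiple crystals.
    Datasets are screened for unit-cell isomorphism with the absolute linear
    cell variation (aLCV) metric, grouped by hierarchical cluster analysis of
    symmetry-aware cell descriptors, jointly scaled (per-dataset scale and
    isotropic B factor) and merged into candidate complete datasets with full
    merging statistics (Rmerge, Rmeas, Rpim, CC1/2, completeness,
    multiplicity), and improved by greedy dataset filtering and
    radiation-damage-aware trailing-image pruning.  A synthetic multi-crystal
    campaign simulator with known ground truth makes every step testable
    without real diffraction data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
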