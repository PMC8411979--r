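Package: nucval
Title: Watson-Crick Base-Pair Geometry Validation and Restraints for Nucleic Acid Structure Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects Watson-Crick base pairs in nucleic acid structure models
    (PDB and mmCIF), measures base-pair hydrogen-bond lengths and the four
    "simple" base-pair parameters (shear, stretch, buckle, propeller) in
    standard-reference-frame geometry, and validates them against mined
    target tables via per-pair Z_bpG scores and model-level rmsZ metrics
    with jackknife standard deviations. Generates refinement-ready external
    hydrogen-bond and base-stacking restraints with a resolution gate, and
    re-derives target tables from annotated structure collections with
    RSCC/resolution filtering, Welch-test pooling and a resolution sweep.
    Includes a synthetic base-pair and duplex builder that inverts the
    measurement pipeline for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
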