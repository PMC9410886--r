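Package: dnaform
Title: A/B-Form DNA Geometry and A-Philicity Profiling of Retroviral
    Integration Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify target-DNA deformation during retroviral
    integration. Parses nucleic-acid structures (PDB/mmCIF), fits standard
    base reference frames, computes base-pair step parameters (shift, slide,
    rise, tilt, roll, twist), the Zp phosphorus statistic, glycosidic torsion
    chi, major/minor groove widths and protein-DNA contacts, and classifies
    each dinucleotide step as A-form, B-form or intermediate. Generates
    idealized A- and B-form fiber duplexes as geometric references. Profiles
    sequence-intrinsic B-to-A transition free energies (trinucleotide
    dG(B->A)) across aligned integration-site windows anchored at the site of
    viral DNA joining, detects A-philic peak spacing at the target-site
    duplication, and computes integration-site sequence statistics (base
    frequency matrices, YR/RY dinucleotide usage, degenerate consensus,
    3'-processing arithmetic and the branched strand-transfer substrate
    model). A seeded simulator generates integration-site windows and
    synthetic genomes with planted signals so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
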