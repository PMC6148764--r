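Package: consenz
Title: Structure-Guided Consensus Design and Enzyme Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for structure-guided consensus engineering of enzymes
    and for the downstream biochemical characterization of the resulting
    variants. Curates homolog sets from a multiple sequence alignment
    (identity window and redundancy removal), computes per-column residue
    frequency profiles and consensus calls mapped onto a target sequence,
    builds neighbor-joining trees to select branch representatives, applies
    structure-based candidate filters (active-site proximity, surface/core
    hydrophobicity match via Shrake-Rupley solvent-accessible surface area,
    and side-chain interaction compatibility), designs NNK/MNN
    saturation-mutagenesis primer pairs with exact library-coverage
    statistics, and fits first-order thermal inactivation, two-state
    melting and Michaelis-Menten models with wild-type-relative comparison
    reports. Seeded synthetic generators produce every input type so the
    full workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
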