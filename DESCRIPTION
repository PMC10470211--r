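Package: carotenostruct
Title: Geometry and Interaction Analysis of Carotenoid-Binding Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural descriptors for carotenoprotein complexes: bond length
    alternation (BLA) of conjugated polyenes, signed torsions and end-ring
    s-cis/s-trans classification, polyene plane-pair geometry, pseudo-twofold
    axis relations, protein-ligand contact shells, hydrogen-bond detection,
    Shrake-Rupley solvent-accessible surface area partitioning across subunits,
    fragment B-factor statistics, sequence-guided Kabsch superposition, and
    supporting sequence (N-glycosylation sequons, signal-peptide bookkeeping,
    conserved cysteines, monoisotopic masses) and absorption-spectrum
    (lambda-max, bathochromic shift) utilities. Includes a synthetic-structure
    generator with known ground truth so the whole pipeline is testable without
    downloading deposited structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
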