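Package: ablineage
Title: Antibody Lineage Analysis of the Phl p 5-Specific Clonotype 212579
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Germline-anchored IMGT numbering, unmutated-common-ancestor (UCA)
    inference and junction base accounting for antibody variable-domain
    rearrangements, together with the quantitative analyses used to
    characterize the grass-pollen-allergen (Phl p 5) specific antibody 212579
    and its lineage variants: reversion-variant and site-directed mutagenesis
    primer design, global 1:1 Langmuir fitting of surface plasmon resonance
    sensorgrams, first-derivative melting-temperature extraction from
    nanoDSF-style melt curves, hydrodynamic radii from Taylor dispersion
    analysis, and exact Mann-Whitney comparison of small variant groups.
    Synthetic-data generators emulate V(D)J rearrangement with somatic
    hypermutation and the instrument traces, so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
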