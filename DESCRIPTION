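Package: mdscreen
Title: Proteomic and Phenotypic Screen Analysis for MDSC-Directed Drug Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for myeloid-derived suppressor cell (MDSC)
    drug-discovery data: reading and filtering MaxQuant-style protein-group
    and phosphosite tables, TMT reporter-ion normalization (total-sum,
    median-centering, bridge-channel, proteome-ratio normalization of
    phosphosites), two-group differential expression with an S0-moderated
    t statistic and permutation or Benjamini-Hochberg false discovery rate,
    coculture-screen percent-effect normalization and hit calling with a
    T-cell counter-screen filter, dose-response (4PL) and competition-pulldown
    (5PL, fixed top) curve fitting with depletion-corrected apparent Kd,
    solvent-induced protein precipitation (SIP) stabilization analysis, and
    small plate-assay calculators. Seeded synthetic-data generators emulate
    every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
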