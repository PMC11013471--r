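Package: selectGS
Title: Selective Genotyping and Phenotyping for Genomic Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing the allocation of genotyping and phenotyping
    resources in genomic selection. Implements ridge-regression BLUP (RR-BLUP)
    genomic prediction with REML variance-component estimation, sliding-window
    linkage-disequilibrium pruning, four low-density marker-panel selection
    strategies (effect-ranked with and without re-estimation, random, and
    best-of-random-models), identity-by-state based core-set selection under
    entry-to-nearest-entry (EN) and accession-to-nearest-entry (AN) objectives,
    and cross-validation / external-validation experiment drivers. A synthetic
    population generator emulates biparental recombinant inbred line,
    multifamily breeding panel, and structured germplasm collection archetypes
    with linkage-disequilibrium block structure, additive polygenic trait
    architecture, and controllable heritability, so the whole workflow is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
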