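Package: SH2generic
Title: Generic Residue Numbering and Structural Comparison for SH2 Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a generic residue numbering scheme for SH2
    (Src-homology 2) domains, analogous to the Ballesteros-Weinstein
    scheme for GPCRs: each conserved secondary-structure segment carries
    an x50 anchor at its most conserved position, with neighbours
    numbered sequentially, enabling cross-protein comparison of
    equivalent positions such as the phosphotyrosine-anchoring arginine
    bBx50. Provides tools to derive numbering from multiple sequence
    alignments, annotate new sequences, renumber and trim PDB structures
    to wild-type SH2 domains, superpose domains on the core beta-sheet
    (strands bB, bC, bD) by least-squares rigid-body fitting, build
    neighbor-joining trees from numbered-position sub-alignments, export
    molecular-viewer session scripts, and generate synthetic SH2-like
    families with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    bio3d,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'SH2generic-package.R'
    'scheme.R'
    'profile-numbering.R'
    'phylo.R'
    'structure-io.R'
    'superposition.R'
    'fixtures.R'
    'cli.R'
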