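Package: swmdesign
Title: Structure-Guided Design and Selection of Mutant rRNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for computationally guided design and screening of
    ribosomal RNA mutant libraries. Extracts fixed structural contexts
    around designable residues from PDB/mmCIF structures, encodes
    anything-but-wildtype libraries with IUPAC ambiguity codes, runs
    Metropolis Monte Carlo identity-design campaigns under a pluggable
    energy model (with a documented base-pairing stand-in score and
    ingestion of external score tables), re-scores fixed sequences with
    an equal forward-folding budget, implements span-the-range,
    top-fraction and randomized-control selection protocols, and
    analyzes screen outputs: wild-type-normalized activity, score-activity
    correlation, Watson-Crick/wobble pair classification, multiplicative
    epistasis deviations, viability concordance, and per-column sequence
    conservation mapped to reference numbering. Includes seeded
    generators for ideal A-form helices, simulated activity screens and
    simulated alignments used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
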