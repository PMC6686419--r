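Package: torsionforge
Type: Package
Title: Torsion Parameter Refitting and Conformer Recovery Benchmarks for
    MMFF94s-Style Force Fields
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Toolkit for analysing and refitting the torsion-angle term of
    MMFF94s-style small-molecule force fields. Implements the three-term
    cosine torsion potential with wildcard-fallback parameter lookup and
    ships both the original wildcard parameters and a refitted parameter
    set for N-aryl amides and phenylpyrroles; builds canonical TorsionID
    strings describing the local chemical environment of rotatable bonds;
    computes symmetry-corrected dihedral deviations; runs a random-dihedral
    conformer generation and bioactive-conformation recovery benchmark with
    a pluggable energy engine; and refits (V1, V2, V3) barrier triples to
    reference potential-energy-surface scans by systematic grid search or
    a genetic algorithm with summed-RMSD fitness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    bio3d,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
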